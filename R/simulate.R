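# Seeded synthetic gene families: random trees, alignments evolved under
# a uniform (Jukes-Cantor-style) substitution process with planted driver
# and compensator transitions, taxon annotations, tumor mutation tables
# and structure hit tables. Ground-truth event logs are first-class
# outputs so tests never re-derive truth from simulator internals.

#' Simulate a random rooted gene tree
#'
#' A random binary rooted topology with independent exponential branch
#' lengths (mean `1/branch_rate` substitutions per site), deterministic
#' under `seed`.
#'
#' @param n_leaves number of leaves (>= 4).
#' @param branch_rate rate of the exponential branch-length distribution.
#' @param seed optional seed.
#' @return An ape `phylo` with tip labels `s1..sN`.
#' @export
simulate_tree <- function(n_leaves, branch_rate = 10, seed = NULL) {
  if (n_leaves < 4) abort("n_leaves must be >= 4")
  if (!is.null(seed)) set.seed(seed)
  phy <- ape::rtree(n_leaves, rooted = TRUE, br = stats::rexp,
                    rate = branch_rate)
  phy$tip.label <- paste0("s", seq_len(n_leaves))
  phy
}

#' Assign major clades and a toy taxonomy to tree leaves
#'
#' Leaves are taken in tree traversal order and split into contiguous
#' blocks assigned to the six major clades according to `proportions`
#' (clades with a zero share are omitted). Each leaf is its own species;
#' species are grouped into "families" of up to four along the taxonomy
#' path root; clade; family; species.
#'
#' @param tree an ape `phylo`.
#' @param proportions named shares over the major clades (normalized).
#' @return A taxon annotation tibble (`seq_id`, `species`, `clade`,
#'   `path`).
#' @export
simulate_taxa <- function(tree, proportions = c(
                            vertebrate = 0.35, invertebrate = 0.25,
                            protist = 0.1, fungus = 0.1, plant = 0.1,
                            prokaryote = 0.1)) {
  proportions <- proportions[names(proportions) %in% MAJOR_CLADES]
  proportions <- proportions / sum(proportions)
  idx <- tree_index(tree)
  tip_order <- idx$preorder[idx$preorder <= idx$n_tip]
  n <- length(tip_order)
  sizes <- floor(proportions * n)
  while (sum(sizes) < n) sizes[which.max(proportions * n - sizes)] <-
    sizes[which.max(proportions * n - sizes)] + 1
  clade <- rep(names(sizes), sizes)
  labels <- idx$tip_label[tip_order]
  # family numbering restarts within each (contiguous) clade block
  fam <- stats::ave(seq_len(n), clade, FUN = function(i) ceiling(seq_along(i) / 4))
  tibble(
    seq_id = labels, species = labels, clade = clade,
    path = paste("root", clade, paste0(clade, "_fam", fam), labels, sep = ";")
  )
}

# Validate planted events: compensators must sit on the same branch as,
# or an ancestor branch of, every driver event they are tied to.
validate_events <- function(idx, events) {
  if (is.null(events) || nrow(events) == 0) return(invisible(NULL))
  need <- c("site", "node", "to", "role")
  if (!all(need %in% names(events))) {
    abort(sprintf("events need columns: %s", paste(need, collapse = ", ")))
  }
  comp <- events[events$role == "compensator", ]
  if (nrow(comp) && "driver_site" %in% names(events)) {
    # every driver event must descend from (or share the branch of) at
    # least one compensator origin tied to its site
    for (ds in unique(comp$driver_site)) {
      cn <- comp$node[comp$driver_site == ds]
      dn <- events$node[events$role == "driver" & events$site == ds]
      ok <- vapply(dn, function(d) any(vapply(cn, function(c)
        is_ancestor_or_self(idx, c, d), logical(1))), logical(1))
      if (length(ok) && !all(ok)) {
        abort("compensator events do not precede all of their driver events")
      }
    }
  }
  invisible(NULL)
}

#' Evolve an alignment on a tree with planted events
#'
#' Sequences evolve from a root sequence down the tree under a uniform
#' substitution process: on a branch of length `l` each site mutates with
#' probability `1 - exp(-sub_rate * l)` to a uniformly chosen different
#' residue. Planted events overwrite the state at their site on the
#' chosen branch (identified by its child node) and propagate to all
#' descendants; random substitutions at planted sites are suppressed so
#' the planted history is exact. The true substitution history is
#' returned as an event log.
#'
#' @param tree an ape `phylo`.
#' @param n_sites alignment length.
#' @param sub_rate substitution rate per site per unit branch length.
#' @param events optional tibble of planted events with columns `site`,
#'   `node` (child node of the branch), `to` (derived residue), `role`
#'   (`"driver"` or `"compensator"`), optionally `driver_site` tying a
#'   compensator to its driver's site for precedence validation.
#' @param root_seq optional root sequence (character vector of length
#'   `n_sites`); sampled uniformly otherwise.
#' @param seed optional seed.
#' @return List with `sequences` (named character vector of leaf
#'   sequences), `truth` (tibble `site`, `parent`, `child`, `from`, `to`,
#'   `role`), `root_seq`.
#' @export
simulate_alignment <- function(tree, n_sites = 60, sub_rate = 0.1,
                               events = NULL, root_seq = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  idx <- tree_index(tree)
  validate_events(idx, events)
  root_seq <- root_seq %||% sample(AA20, n_sites, replace = TRUE)
  planted_sites <- if (is.null(events)) integer(0) else unique(events$site)
  seqs <- matrix(NA_character_, idx$n_all, n_sites)
  seqs[idx$root, ] <- root_seq
  log <- list()
  for (v in idx$preorder) {
    if (v == idx$root) next
    p <- idx$parent[v]
    s <- seqs[p, ]
    l <- idx$blen_in[v]
    pmut <- 1 - exp(-sub_rate * l)
    mut <- stats::runif(n_sites) < pmut
    mut[planted_sites] <- FALSE
    for (j in which(mut)) {
      new <- sample(setdiff(AA20, s[j]), 1)
      log[[length(log) + 1L]] <- tibble(site = j, parent = p, child = v,
                                        from = s[j], to = new,
                                        role = "background")
      s[j] <- new
    }
    if (!is.null(events)) {
      ev <- events[events$node == v, ]
      for (k in seq_len(nrow(ev))) {
        log[[length(log) + 1L]] <- tibble(site = ev$site[k], parent = p,
                                          child = v, from = s[ev$site[k]],
                                          to = ev$to[k], role = ev$role[k])
        s[ev$site[k]] <- ev$to[k]
      }
    }
    seqs[v, ] <- s
  }
  truth <- if (length(log)) dplyr::bind_rows(log) else
    tibble(site = integer(), parent = integer(), child = integer(),
           from = character(), to = character(), role = character())
  leaf_seqs <- apply(seqs[seq_len(idx$n_tip), , drop = FALSE], 1,
                     paste0, collapse = "")
  names(leaf_seqs) <- idx$tip_label
  list(sequences = leaf_seqs, truth = truth, root_seq = root_seq)
}

# Plant a compensated-driver configuration on a tree.
#
# The compensator state arises independently at `n_origins` disjoint
# internal nodes; the driver arises at `n_driver_events` small clades
# ("cherries" of 2-3 leaves) distributed among the origins. Two weighted
# minority constraints make the planted history exactly recoverable by
# the weighted two-pass reconstruction: at every strict ancestor of a
# planted node the leaf weight carrying the derived state stays below
# `max_frac` (< 1/2), so no ancestral node is pulled to the derived
# residue and each transition stays on its planted branch. The exact
# occupancy fraction F of the origins (full subtree lengths plus half
# incoming branches over the total tree length) then gives the binomial
# co-occurrence probability F^n_driver_events, and a configuration is
# only accepted when that probability is below `p_target`. Returns NULL
# when the topology admits no such configuration.
plant_configuration <- function(idx, n_origins = 2, n_driver_events = 4,
                                max_frac = 0.45, p_target = 0.009) {
  w <- leaf_weights(idx)
  n_tip <- idx$n_tip
  sw <- numeric(idx$n_all)          # leaf weight below each node
  sub <- numeric(idx$n_all)         # branch length below each node
  for (v in idx$postorder) {
    ch <- idx$children[[v]]
    if (!length(ch)) {
      sw[v] <- w$leaf[idx$tip_label[v]]
    } else {
      sw[v] <- sum(sw[ch])
      sub[v] <- sum(idx$blen_in[ch] + sub[ch])
    }
  }
  total_len <- sub[idx$root]
  internals <- setdiff(seq_len(idx$n_all)[-seq_len(n_tip)], idx$root)
  sizes <- lengths(idx$tips_below)
  cherries <- internals[sizes[internals] %in% c(2L, 3L)]
  footprint <- idx$blen_in / 2 + sub
  # events per origin, as even as possible
  quota <- rep(n_driver_events %/% n_origins, n_origins)
  if (n_driver_events %% n_origins) {
    quota[seq_len(n_driver_events %% n_origins)] <-
      quota[seq_len(n_driver_events %% n_origins)] + 1
  }
  minority_ok <- function(nodes_weight_below) {
    # nodes_weight_below: named vector node -> planted weight below it
    all(nodes_weight_below < max_frac * sw[as.integer(names(nodes_weight_below))])
  }
  planted_weight_at_ancestors <- function(planted) {
    acc <- list()
    for (v in planted) {
      for (a in node_ancestors(idx, v)) {
        key <- as.character(a)
        acc[[key]] <- (acc[[key]] %||% 0) + sw[v]
      }
    }
    unlist(acc) %||% numeric(0)
  }
  pick_cherries <- function(origin, q, forbidden) {
    pool <- cherries[vapply(cherries, function(v)
      v != origin && is_ancestor_or_self(idx, origin, v), logical(1))]
    pool <- setdiff(pool, forbidden)
    chosen <- integer(0)
    for (v in pool[order(sw[pool])]) {
      trial <- c(chosen, v)
      disjoint <- all(vapply(chosen, function(u)
        !is_ancestor_or_self(idx, u, v) && !is_ancestor_or_self(idx, v, u),
        logical(1)))
      if (!disjoint) next
      if (minority_ok(planted_weight_at_ancestors(trial))) chosen <- trial
      if (length(chosen) == q) break
    }
    if (length(chosen) == q) chosen else NULL
  }
  origin_pool <- internals[order(footprint[internals])]
  origin_pool <- origin_pool[sizes[origin_pool] >= 2 * max(quota) + 1]
  for (i in seq_along(origin_pool)) {
    c1 <- origin_pool[i]
    rest <- origin_pool[-seq_len(i)]
    rest <- rest[vapply(rest, function(v)
      !is_ancestor_or_self(idx, c1, v) && !is_ancestor_or_self(idx, v, c1),
      logical(1))]
    partners <- if (n_origins == 1) list(integer(0)) else as.list(rest)
    for (c2 in partners) {
      origins <- c(c1, c2)
      f <- sum(footprint[origins]) / total_len
      if (f^n_driver_events >= p_target) next
      if (!minority_ok(planted_weight_at_ancestors(origins))) next
      drivers <- integer(0)
      ok <- TRUE
      for (k in seq_along(origins)) {
        ck <- pick_cherries(origins[k], quota[k], drivers)
        if (is.null(ck)) {
          ok <- FALSE
          break
        }
        drivers <- c(drivers, ck)
      }
      if (!ok) next
      if (!minority_ok(planted_weight_at_ancestors(drivers))) next
      return(list(origins = origins, drivers = drivers, f = f,
                  p = f^n_driver_events))
    }
  }
  NULL
}

# Driver-only (null) configuration: driver cherries drawn independently
# across the whole tree (random order, disjointness and the weighted
# minority rule as the only constraints), with no compensator. Keeping
# the events dispersed is what makes this a proper null: their placement
# carries no signal any single ancestral state could explain.
plant_driver_only <- function(idx, n_driver_events = 4, max_frac = 0.45) {
  w <- leaf_weights(idx)
  sw <- numeric(idx$n_all)
  for (v in idx$postorder) {
    ch <- idx$children[[v]]
    sw[v] <- if (length(ch)) sum(sw[ch]) else w$leaf[idx$tip_label[v]]
  }
  internals <- setdiff(seq_len(idx$n_all)[-seq_len(idx$n_tip)], idx$root)
  cherries <- internals[lengths(idx$tips_below)[internals] %in% c(2L, 3L)]
  minority_ok <- function(planted) {
    acc <- list()
    for (v in planted) {
      for (a in node_ancestors(idx, v)) {
        key <- as.character(a)
        acc[[key]] <- (acc[[key]] %||% 0) + sw[v]
      }
    }
    all(unlist(acc) < max_frac * sw[as.integer(names(acc))])
  }
  chosen <- integer(0)
  for (v in sample(cherries)) {
    disjoint <- all(vapply(chosen, function(u)
      !is_ancestor_or_self(idx, u, v) && !is_ancestor_or_self(idx, v, u),
      logical(1)))
    if (!disjoint) next
    if (minority_ok(c(chosen, v))) chosen <- c(chosen, v)
    if (length(chosen) == n_driver_events) break
  }
  if (length(chosen) < n_driver_events) return(NULL)
  list(drivers = chosen)
}

#' Simulate a tumor mutation table
#'
#' Each mutation is present in each tumor by an independent Bernoulli
#' draw at its marginal frequency, except for configured pairs which are
#' drawn jointly from a 2x2 table whose co-occurrence cell is the product
#' of the marginals times the odds multiplier.
#'
#' @param n_tumors number of tumor samples.
#' @param mutations tibble with `gene`, `ref_aa`, `pos`, `alt_aa`,
#'   `freq`, `snp`, `class`.
#' @param pairs optional tibble with `i`, `j` (row indices into
#'   `mutations`) and `multiplier`.
#' @param seed optional seed.
#' @return Tibble of mutation records (one row per present mutation per
#'   tumor) with attribute `n_tumors`.
#' @export
simulate_tumor_table <- function(n_tumors, mutations, pairs = NULL,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(mutations$freq < 0 | mutations$freq > 1)) {
    abort("mutation frequencies must be in [0, 1]")
  }
  m <- nrow(mutations)
  present <- matrix(FALSE, n_tumors, m)
  paired <- logical(m)
  if (!is.null(pairs) && nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      i <- pairs$i[r]; j <- pairs$j[r]; mult <- pairs$multiplier[r]
      p1 <- mutations$freq[i]; p2 <- mutations$freq[j]
      p11 <- mult * p1 * p2
      p10 <- p1 - p11; p01 <- p2 - p11; p00 <- 1 - p1 - p2 + p11
      if (p11 > min(p1, p2) + 1e-12 || p00 < -1e-12 || p10 < -1e-12 ||
          p01 < -1e-12) {
        abort(sprintf(
          "infeasible pair: marginals %.3f/%.3f with multiplier %.2f", p1, p2, mult))
      }
      cell <- sample(4, n_tumors, replace = TRUE,
                     prob = pmax(c(p11, p10, p01, p00), 0))
      present[, i] <- cell %in% c(1L, 2L)
      present[, j] <- cell %in% c(1L, 3L)
      paired[c(i, j)] <- TRUE
    }
  }
  for (i in which(!paired)) {
    present[, i] <- stats::runif(n_tumors) < mutations$freq[i]
  }
  hit <- which(present, arr.ind = TRUE)
  out <- tibble(
    gene = mutations$gene[hit[, 2]],
    sample_id = sprintf("T%05d", hit[, 1]),
    ref_aa = mutations$ref_aa[hit[, 2]],
    pos = mutations$pos[hit[, 2]],
    alt_aa = mutations$alt_aa[hit[, 2]],
    snp = mutations$snp[hit[, 2]],
    class = mutations$class[hit[, 2]]
  ) |> dplyr::arrange(.data$sample_id, .data$pos)
  attr(out, "n_tumors") <- n_tumors
  out
}

#' Simulate a complete toy gene family
#'
#' Generates a tree, taxon annotations, an alignment with planted driver
#' transitions (and, unless `plant = "driver_only"`, a compensator
#' transition on an ancestral branch covering all driver events), a tumor
#' table in which the planted driver is the most recurrent missense
#' mutation, and a synthetic structure hit table. The human reference row
#' is a vertebrate leaf outside the compensator subtree, so the reference
#' carries neither planted state.
#'
#' @param seed seed fixing the whole bundle.
#' @param n_leaves,branch_rate,n_sites,sub_rate simulation parameters
#'   (see [simulate_tree], [simulate_alignment]).
#' @param n_driver_events number of independent driver transitions to
#'   plant.
#' @param n_comp_origins number of independent compensator origins
#'   (ignored for `"driver_only"`).
#' @param plant `"compensated"` plants driver and preceding compensator;
#'   `"driver_only"` plants only the driver (the null for calibration).
#' @param n_tumors tumor samples in the mutation table.
#' @param driver_freq per-tumor frequency of the planted driver mutation.
#' @param n_noise_mutations additional random missense mutations.
#' @param pair_multiplier odds multiplier tying the driver to the first
#'   noise mutation in tumors (1 = independent).
#' @param gene gene id used throughout.
#' @param max_attempts trees resampled until one admits a planted
#'   configuration.
#' @return List with `family` ([gene_family]), `tumor_table`, `n_tumors`,
#'   `hits` (scored-ready hit table), `truth` (planted + background event
#'   log), `driver` (tibble `pos`, `ref_aa`, `alt_aa`, `column`),
#'   `compensator` (tibble `site`, `residue`, `node` (one row per
#'   origin), or NULL), `config`.
#' @export
simulate_gene_family <- function(seed = 1, n_leaves = 96, branch_rate = 10,
                                 n_sites = 60, sub_rate = 0.1,
                                 n_driver_events = 4, n_comp_origins = 2,
                                 plant = c("compensated", "driver_only"),
                                 n_tumors = 500, driver_freq = 0.08,
                                 n_noise_mutations = 8,
                                 pair_multiplier = 1, gene = "GENE1",
                                 max_attempts = 25) {
  plant <- match.arg(plant)
  cfg <- NULL
  for (attempt in seq_len(max_attempts)) {
    set.seed(seed + (attempt - 1L) * 1000003L)
    tree <- simulate_tree(n_leaves, branch_rate)
    idx <- tree_index(tree)
    cfg <- if (plant == "compensated") {
      plant_configuration(idx, n_origins = n_comp_origins,
                          n_driver_events = n_driver_events)
    } else {
      plant_driver_only(idx, n_driver_events = n_driver_events)
    }
    if (!is.null(cfg)) break
  }
  if (is.null(cfg)) {
    abort("no tree admitted a planting configuration; use more leaves")
  }
  taxa <- simulate_taxa(tree)
  root_seq <- sample(AA20, n_sites, replace = TRUE)
  driver_site <- floor(n_sites / 2)
  comp_site <- floor(n_sites / 4)
  driver_res <- sample(setdiff(AA20, root_seq[driver_site]), 1)
  comp_res <- sample(setdiff(AA20, root_seq[comp_site]), 1)
  events <- tibble(
    site = driver_site, node = cfg$drivers, to = driver_res,
    role = "driver", driver_site = NA_integer_)
  if (plant == "compensated") {
    events <- dplyr::bind_rows(
      tibble(site = comp_site, node = cfg$origins, to = comp_res,
             role = "compensator", driver_site = driver_site),
      events)
  }
  sim <- simulate_alignment(tree, n_sites = n_sites, sub_rate = sub_rate,
                            events = events, root_seq = root_seq)
  # reference: a vertebrate leaf carrying neither planted state
  planted_nodes <- c(cfg$origins %||% integer(0), cfg$drivers)
  inside <- idx$tip_label[unique(unlist(idx$tips_below[planted_nodes]))]
  vert <- taxa$seq_id[taxa$clade == "vertebrate"]
  ref_candidates <- setdiff(vert, inside)
  if (length(ref_candidates) == 0) ref_candidates <- setdiff(idx$tip_label, inside)
  reference_id <- ref_candidates[1]
  aln <- msa(sim$sequences, reference_id)
  family <- suppressMessages(gene_family(aln, tree, taxa, gene = gene))
  # tumor table: the driver plus noise mutations at other reference sites
  ref_row <- aln$mat[reference_id, ]
  driver_pos <- match(driver_site, family$ref_map$column)
  noise_sites <- sample(setdiff(seq_len(n_sites), c(driver_site, comp_site)),
                        n_noise_mutations + 2)
  make_mut <- function(site, freq, snp, class) {
    ref <- ref_row[site]
    alt <- if (class == "nonsense") "*" else sample(setdiff(AA20, ref), 1)
    tibble(gene = gene, ref_aa = unname(ref),
           pos = match(site, family$ref_map$column),
           alt_aa = unname(alt), freq = freq, snp = snp, class = class)
  }
  muts <- dplyr::bind_rows(
    tibble(gene = gene, ref_aa = unname(ref_row[driver_site]),
           pos = driver_pos, alt_aa = driver_res, freq = driver_freq,
           snp = FALSE, class = "missense"),
    dplyr::bind_rows(lapply(seq_len(n_noise_mutations), function(i) {
      # background somatic mutations are rare: well under 2% of tumors
      make_mut(noise_sites[i], stats::runif(1, 0.002, 0.02), FALSE, "missense")
    })),
    make_mut(noise_sites[n_noise_mutations + 1], 0.03, FALSE, "nonsense"),
    make_mut(noise_sites[n_noise_mutations + 2], 0.1, TRUE, "missense")
  )
  muts$alt_aa[muts$class == "nonsense"] <- "*"
  pairs <- if (pair_multiplier != 1) {
    tibble(i = 1L, j = 2L, multiplier = pair_multiplier)
  } else NULL
  tumor_table <- simulate_tumor_table(n_tumors, muts, pairs = pairs)
  hits <- synthetic_structure_hits(gene, n_sites, driver_pos)
  list(
    family = family, tumor_table = tumor_table, n_tumors = n_tumors,
    hits = hits, truth = sim$truth,
    driver = tibble(pos = driver_pos, ref_aa = unname(ref_row[driver_site]),
                    alt_aa = driver_res, column = driver_site),
    compensator = if (plant == "compensated") {
      tibble(site = comp_site, residue = comp_res, node = cfg$origins)
    } else NULL,
    config = list(seed = seed, n_leaves = n_leaves, branch_rate = branch_rate,
                  n_sites = n_sites, sub_rate = sub_rate,
                  n_driver_events = n_driver_events,
                  n_comp_origins = n_comp_origins, plant = plant,
                  n_tumors = n_tumors, driver_freq = driver_freq,
                  pair_multiplier = pair_multiplier)
  )
}

# A small deterministic synthetic hit table (labelled synthetic: these
# are not real PDB entries): one full-length structure, one N-terminal
# domain with a strong local score, one weak C-terminal fragment.
synthetic_structure_hits <- function(gene, protein_length, driver_pos) {
  half <- floor(protein_length / 2)
  tibble(
    query = gene,
    subject = c("SYN1_A", "SYN2_A", "SYN3_B"),
    pident = c(95, 90, 40),
    length = c(protein_length, half, protein_length - half),
    mismatch = c(3, 5, 30),
    gapopen = c(0, 0, 2),
    qstart = c(1L, 1L, half + 1L),
    qend = c(protein_length, half, protein_length),
    sstart = c(1L, 1L, 1L),
    send = c(protein_length, half, protein_length - half),
    evalue = c(1e-80, 1e-40, 1e-5),
    bitscore = c(2 * protein_length, 2.2 * half, 0.8 * (protein_length - half)),
    structure = c("SYN1", "SYN2", "SYN3"),
    chain = c("A", "A", "B")
  )
}

#' Write a simulated gene family bundle to disk
#'
#' Emits the same plain-text dialects the readers consume: aligned FASTA,
#' Newick, taxon TSV, mutation TSV and a 12-column hit TSV.
#'
#' @param bundle output of [simulate_gene_family].
#' @param dir output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_gene_family <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    msa = file.path(dir, "alignment.fasta"),
    tree = file.path(dir, "tree.nwk"),
    taxa = file.path(dir, "taxa.tsv"),
    mutations = file.path(dir, "mutations.tsv"),
    hits = file.path(dir, "structure_hits.tsv")
  )
  write_msa(bundle$family$msa, paths[["msa"]])
  ape::write.tree(bundle$family$tree, file = paths[["tree"]])
  utils::write.table(bundle$family$taxa, paths[["taxa"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$tumor_table, paths[["mutations"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cols <- c("query", "subject", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  utils::write.table(bundle$hits[cols], paths[["hits"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(paths)
}
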
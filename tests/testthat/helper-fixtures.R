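# Small fixtures built in code.

AA20 <- phylocomp:::AA20
`%||%` <- function(a, b) if (is.null(a)) b else a
validate_offset_rules <- phylocomp:::validate_offset_rules

# A 4-row toy alignment with a gapped reference.
toy_msa <- function() {
  msa(c(HUMAN = "M-KTA", A = "MAKTA", B = "MAKSA", C = "M-RTA"),
      reference_id = "HUMAN")
}

# A 5-leaf family with hand-chosen branch lengths, one clade per block.
toy_family <- function() {
  tree <- ape::read.tree(text = "(((a:1,b:1):1,(c:1,d:1):1):1,e:4);")
  aln <- msa(c(a = "MAKTA", b = "MAKTA", c = "MVKTA", d = "MVKTA",
               e = "MAKTA", HUMAN = "MAKTA"),
             reference_id = "HUMAN")
  taxa <- tibble::tibble(
    seq_id = c("a", "b", "c", "d", "e", "HUMAN"),
    species = c("a", "b", "c", "d", "e", "HUMAN"),
    clade = c("vertebrate", "vertebrate", "invertebrate", "invertebrate",
              "fungus", "vertebrate"),
    path = c("root;vertebrate;a", "root;vertebrate;b",
             "root;invertebrate;c", "root;invertebrate;d",
             "root;fungus;e", "root;vertebrate;HUMAN"))
  suppressWarnings(gene_family(aln, tree, taxa, gene = "TOY"))
}

# Random site pattern on a random small tree, for oracle comparisons.
random_small_case <- function(n_tip = 6, n_res = 3, gap_p = 0.2) {
  phy <- ape::rtree(n_tip, br = stats::rexp, rate = 2)
  chars <- sample(c(AA <- c("A", "V", "T", "R")[seq_len(n_res)], NA),
                  n_tip, replace = TRUE,
                  prob = c(rep((1 - gap_p) / n_res, n_res), gap_p))
  list(phy = phy, chars = chars)
}

# Wrap a bare tree + site pattern into a gene_family for package calls.
family_from_case <- function(phy, chars) {
  seqs <- ifelse(is.na(chars), "-", chars)
  seqs <- stats::setNames(paste0(seqs, "A"), phy$tip.label)
  aln <- msa(seqs, reference_id = phy$tip.label[1])
  taxa <- tibble::tibble(seq_id = phy$tip.label, species = phy$tip.label,
                         clade = "vertebrate",
                         path = paste0("root;vertebrate;", phy$tip.label))
  gene_family(aln, phy, taxa, gene = "CASE")
}

# Random mutation tables for rank brute-force checks.
random_mutation_table <- function(n_mut = 50, n_tumors = 60) {
  muts <- tibble::tibble(
    gene = "G",
    ref_aa = sample(c("A", "R", "K", "T"), n_mut, replace = TRUE),
    pos = sample(1:200, n_mut),
    alt_aa = "W",
    snp = stats::runif(n_mut) < 0.1,
    class = sample(c("missense", "nonsense", "other"), n_mut,
                   replace = TRUE, prob = c(0.7, 0.2, 0.1))
  )
  rows <- lapply(seq_len(n_mut), function(i) {
    k <- stats::rpois(1, 3) + 1
    tibble::tibble(gene = "G", sample_id = paste0("T", sample(n_tumors, k)),
                   ref_aa = muts$ref_aa[i], pos = muts$pos[i],
                   alt_aa = muts$alt_aa[i], snp = muts$snp[i],
                   class = muts$class[i])
  })
  dplyr::bind_rows(rows)
}
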
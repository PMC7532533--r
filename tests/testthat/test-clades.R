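mk_species_family <- function() {
  # two species with paralogs, one singleton
  phy <- ape::read.tree(text = "(((a1:1,a2:1):1,b1:1):1,(b2:1,c1:1):1);")
  aln <- msa(c(a1 = "VA", a2 = "VA", b1 = "IA", b2 = "VA", c1 = "-A",
               HUMAN = "VA"),
             reference_id = "HUMAN")
  taxa <- tibble::tibble(
    seq_id = c("a1", "a2", "b1", "b2", "c1", "HUMAN"),
    species = c("spA", "spA", "spB", "spB", "spC", "human"),
    clade = c(rep("invertebrate", 5), "vertebrate"),
    path = c(rep("root;invertebrate;famAB;spA", 2),
             rep("root;invertebrate;famAB;spB", 2),
             "root;invertebrate;famC;spC",
             "root;vertebrate;human"))
  suppressWarnings(gene_family(aln, phy, taxa))
}

test_that("species mode residues follow majority with reference tie-break", {
  fam <- mk_species_family()
  expect_equal(species_mode_residue(fam$msa, fam$taxa, "spA", 1), "V")
  # spB: one V, one I -> tie broken toward the human reference V
  expect_equal(species_mode_residue(fam$msa, fam$taxa, "spB", 1), "V")
  # single-row species returns its own residue (here a gap)
  expect_equal(species_mode_residue(fam$msa, fam$taxa, "spC", 1), "-")
  # lexicographic tie-break when the reference is not among the modes
  aln <- msa(c(x1 = "I", x2 = "L", HUMAN = "V"), "HUMAN")
  taxa <- tibble::tibble(seq_id = c("x1", "x2", "HUMAN"),
                         species = c("spX", "spX", "human"),
                         clade = c("protist", "protist", "vertebrate"),
                         path = c("root;protist;spX", "root;protist;spX",
                                  "root;vertebrate;human"))
  expect_equal(species_mode_residue(aln, taxa, "spX", 1), "I")
})

test_that("clade driver frequencies are leaf-weighted ratios", {
  fam <- toy_family()
  w <- leaf_weights(fam$tree)
  # column 2: A in a,b (vertebrate rows in tree), V in c,d (invertebrate)
  expect_equal(clade_driver_frequency(fam, w, "vertebrate", 2, "A"), 1)
  expect_equal(clade_driver_frequency(fam, w, "vertebrate", 2, "V"), 0)
  expect_equal(clade_driver_frequency(fam, w, "invertebrate", 2, "V"), 1)
  # uniform rescaling of weights leaves frequencies unchanged
  w2 <- w
  w2$leaf <- w$leaf * 11
  expect_equal(clade_driver_frequency(fam, w2, "vertebrate", 2, "A"),
               clade_driver_frequency(fam, w, "vertebrate", 2, "A"))
  # no clade rows with the site: undefined
  aln <- msa(c(a = "M-", b = "M-", c = "MV", d = "MV", e = "MV",
               HUMAN = "MV"), "HUMAN")
  fam2 <- suppressWarnings(gene_family(aln, fam$tree, fam$taxa))
  expect_true(is.na(clade_driver_frequency(fam2, w, "vertebrate", 2, "V")))
})

test_that("weighted frequencies match a hand computation", {
  phy <- ape::read.tree(text = "((a:1,b:3):1,(c:2,d:2):2);")
  aln <- msa(c(a = "V", b = "A", c = "V", d = "A"), "a")
  taxa <- tibble::tibble(seq_id = letters[1:4], species = letters[1:4],
                         clade = "vertebrate",
                         path = paste0("root;vertebrate;", letters[1:4]))
  fam <- gene_family(aln, phy, taxa)
  w <- leaf_weights(phy)
  want <- (w$leaf[["a"]] + w$leaf[["c"]]) / sum(w$leaf)
  expect_equal(clade_driver_frequency(fam, w, "vertebrate", 1, "V"), want)
})

test_that("bootstrap percentiles behave on degenerate and two-point sets", {
  expect_equal(unname(bootstrap_clade_means(rep(0.3, 8), B = 50, seed = 1)),
               rep(0.3, 3))
  one <- bootstrap_clade_means(c(0.2, 0.8), B = 1, seed = 2)
  expect_equal(one[["p25"]], one[["p75"]])
  # balanced 0/1 set of 10: resample means are Binomial(10, 1/2)/10 and
  # the quartiles follow in closed form
  got <- bootstrap_clade_means(rep(c(0, 1), 5), B = 10000, seed = 3)
  want <- stats::qbinom(c(0.25, 0.5, 0.75), 10, 0.5) / 10
  expect_equal(unname(got), want, tolerance = 0.02)
})

test_that("the target clade matches exhaustive evaluation on random
           taxonomies", {
  set.seed(23)
  for (rep in 1:40) {
    n_sp <- sample(10:60, 1)
    phyla <- sample(2:4, 1)
    paths <- vapply(seq_len(n_sp), function(i) {
      ph <- sample(phyla, 1)
      fam <- sample(3, 1)
      paste("root", paste0("phy", ph), paste0("phy", ph, "fam", fam),
            paste0("sp", i), sep = ";")
    }, character(1))
    names(paths) <- paste0("sp", seq_len(n_sp))
    harb <- sample(names(paths), sample(1:n_sp, 1))
    taxa <- tibble::tibble(seq_id = names(paths), species = names(paths),
                           clade = "vertebrate", path = unname(paths))
    got <- find_target_clade(taxa, harb)
    want <- oracle_target_clade(paths, harb, names(paths))
    expect_equal(got$clade, want$clade)
    expect_equal(got$rule, want$rule)
  }
})

test_that("target-clade edge cases: concentrated and singleton drivers", {
  taxa <- tibble::tibble(
    seq_id = paste0("s", 1:6), species = paste0("s", 1:6),
    clade = "vertebrate",
    path = c(rep("root;vertebrate;genusA", 3), rep("root;vertebrate;genusB", 3)))
  taxa$path <- paste(taxa$path, taxa$species, sep = ";")
  # all harboring species inside one genus: that genus, ninety-percent rule
  out <- find_target_clade(taxa, c("s1", "s2", "s3"))
  expect_equal(out$clade, "genusA")
  expect_equal(out$rule, "ninety-percent")
  # a single harboring species: its terminal taxon
  out1 <- find_target_clade(taxa, "s5")
  expect_equal(out1$clade, "s5")
  expect_error(find_target_clade(taxa, character(0)), "no harboring")
})

test_that("species-frequency histogram bins drivers, zero bin included", {
  fam <- mk_species_family()
  drivers <- tibble::tibble(pos = c(1L, 1L, 1L), alt_aa = c("V", "I", "W"),
                            column = c(1L, 1L, 1L))
  out <- species_frequency_histogram(fam, drivers)
  # site present (non-gap mode) in spA, spB, human; V is mode in all 3,
  # I in none (tie lost), W in none
  expect_equal(out$per_driver$fraction, c(1, 0, 0))
  expect_equal(out$histogram$n[out$histogram$bin == "0"], 2L)
  expect_equal(out$histogram$n[out$histogram$bin == "(0.9,1]"], 1L)
  expect_equal(sum(out$histogram$n), 3L)
})

test_that("clade frequency tables bootstrap per clade reproducibly", {
  fam <- toy_family()
  w <- leaf_weights(fam$tree)
  drivers <- tibble::tibble(pos = c(2L, 4L), alt_aa = c("V", "S"),
                            column = c(2L, 4L))
  out1 <- clade_frequency_table(fam, drivers, w, B = 200, seed = 7)
  out2 <- clade_frequency_table(fam, drivers, w, B = 200, seed = 7)
  expect_identical(out1, out2)
  expect_true(all(out1$per_clade$p25 <= out1$per_clade$p50 + 1e-12))
  expect_true(all(out1$per_clade$p50 <= out1$per_clade$p75 + 1e-12))
})
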
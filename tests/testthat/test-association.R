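test_that("tumor pair counts follow the frequency product", {
  # 100 tumors, state1 in 10, state2 in 20, both in 5
  recs <- dplyr::bind_rows(
    tibble::tibble(gene = "G", sample_id = paste0("T", 1:10), ref_aa = "A",
                   pos = 1L, alt_aa = "V", snp = FALSE, class = "missense"),
    tibble::tibble(gene = "G", sample_id = paste0("T", c(1:5, 11:25)),
                   ref_aa = "A", pos = 2L, alt_aa = "W", snp = FALSE,
                   class = "missense"))
  out <- cosmic_pair_counts(recs, 1, "V", 2, "W", n_tumors = 100)
  expect_equal(out$exp, 0.1 * 0.2 * 100)
  expect_equal(out$obs, 5)
  # a state in zero tumors gives zero expected and observed
  out0 <- cosmic_pair_counts(recs, 3, "Y", 2, "W", n_tumors = 100)
  expect_equal(c(out0$exp, out0$obs), c(0, 0))
})

test_that("tumor pair counts equal a tumor-by-tumor brute force", {
  set.seed(13)
  for (rep in 1:10) {
    tab <- random_mutation_table(n_mut = 10, n_tumors = 40)
    states <- dplyr::distinct(tab[, c("pos", "alt_aa")])
    s1 <- states[1, ]
    s2 <- states[2, ]
    got <- cosmic_pair_counts(tab, s1$pos, s1$alt_aa, s2$pos, s2$alt_aa,
                              n_tumors = 40)
    by_tumor <- split(tab, tab$sample_id)
    has <- function(t, s) any(t$pos == s$pos & t$alt_aa == s$alt_aa)
    brute_obs <- sum(vapply(by_tumor, function(t) has(t, s1) && has(t, s2),
                            logical(1)))
    brute_f1 <- sum(vapply(by_tumor, has, logical(1), s = s1)) / 40
    brute_f2 <- sum(vapply(by_tumor, has, logical(1), s = s2)) / 40
    expect_equal(got$obs, brute_obs)
    expect_equal(got$exp, brute_f1 * brute_f2 * 40)
  }
})

test_that("alignment pair counts renormalize weights over qualifying rows", {
  fam <- toy_family()
  w <- leaf_weights(fam$tree)
  # all five tree rows carry M at 1 and A at 5: obs = exp = n
  out <- msa_pair_counts(fam, w, 1, "M", 5, "A")
  expect_equal(out$obs, out$n)
  expect_equal(out$exp, out$n)
  # perfect mutual exclusion at column 2 (A in a,b,e vs V in c,d)
  ex <- msa_pair_counts(fam, w, 2, "A", 2, "V")
  expect_equal(ex$obs, 0)
  wl <- w$leaf / sum(w$leaf)
  pa <- sum(wl[c("a", "b", "e")])
  expect_equal(ex$exp, pa * (1 - pa) * 5)
})

test_that("alignment pair counts match a hand computation with unequal
           weights", {
  phy <- ape::read.tree(text = "((a:1,b:3):1,(c:2,d:2):2);")
  aln <- msa(c(a = "AW", b = "AY", c = "VW", d = "VW"), "a")
  taxa <- tibble::tibble(seq_id = letters[1:4], species = letters[1:4],
                         clade = "vertebrate",
                         path = paste0("root;vertebrate;", letters[1:4]))
  fam <- gene_family(aln, phy, taxa)
  w <- leaf_weights(phy)
  wl <- w$leaf / sum(w$leaf)
  out <- msa_pair_counts(fam, w, 1, "V", 2, "W")
  expect_equal(out$obs, sum(wl[c("c", "d")]) * 4)
  expect_equal(out$exp, sum(wl[c("c", "d")]) * sum(wl[c("a", "c", "d")]) * 4)
})

test_that("the association score has its analytic anchors and matches the
           summation oracle", {
  expect_equal(association_score(3, 0), -3)
  expect_equal(association_score(5, 5), 0)
  set.seed(17)
  for (rep in 1:40) {
    e <- stats::runif(1, 0.1, 50)
    o <- sample(0:200, 1)
    expect_equal(association_score(e, o), oracle_association_score(e, o),
                 tolerance = 1e-6)
  }
  # deep tails survive in log space
  expect_gt(association_score(1, 150), 500)
  expect_lt(association_score(50, 0), -49)
})

test_that("the score is non-decreasing in the observed count", {
  for (e in c(0.5, 3, 20)) {
    s <- association_score(rep(e, 101), 0:100)
    expect_true(all(diff(s) >= 0))
  }
})

test_that("non-integer observed counts enter at the floor by default", {
  expect_equal(association_score(2, 7.9), association_score(2, 7))
  expect_equal(association_score(2, 7.9, obs_mode = "round"),
               association_score(2, 8))
  cont <- association_score(2, 7.5, obs_mode = "continuous")
  expect_gt(cont, association_score(2, 7))
  expect_lt(cont, association_score(2, 8))
})

test_that("pairs with score magnitude at most 1 are discarded and
           quadrants tally signs", {
  recs <- tibble::tibble(
    pos1 = 1:4, res1 = "A", pos2 = 5:8, res2 = "V",
    exp_cosmic = 1, obs_cosmic = 1,
    exp_msa = 1, obs_msa = 1,
    score_cosmic = c(5, -4, 2, 0.5),
    score_msa = c(3, -2, -6, 4))
  recs$kept <- abs(recs$score_cosmic) > 1 & abs(recs$score_msa) > 1
  q <- association_quadrants(recs)
  expect_equal(q$counts$n[match(c("++", "--", "+-", "-+"), q$counts$quadrant)],
               c(1L, 1L, 1L, 0L))
  expect_false(4 %in% q$outliers$pos1)
  # brute-force sign tally on random scores
  set.seed(19)
  rr <- tibble::tibble(
    pos1 = 1:50, res1 = "A", pos2 = 51:100, res2 = "V",
    score_cosmic = stats::runif(50, -5, 5),
    score_msa = stats::runif(50, -5, 5))
  rr$kept <- abs(rr$score_cosmic) > 1 & abs(rr$score_msa) > 1
  q2 <- association_quadrants(rr)
  brute <- table(paste0(ifelse(rr$score_cosmic[rr$kept] > 0, "+", "-"),
                        ifelse(rr$score_msa[rr$kept] > 0, "+", "-")))
  for (qd in names(brute)) {
    expect_equal(q2$counts$n[q2$counts$quadrant == qd], unname(brute[qd]))
  }
})

test_that("the association table pairs drivers with other tumor states", {
  b <- simulate_gene_family(seed = 3)
  recs <- suppressMessages(map_mutations_to_columns(b$tumor_table, b$family))
  w <- leaf_weights(b$family$tree)
  drivers <- dplyr::mutate(b$driver, column = as.integer(column))
  out <- association_table(b$family, recs, drivers, w,
                           n_tumors = b$n_tumors)
  expect_gt(nrow(out), 0)
  key <- paste(drivers$pos, drivers$alt_aa)
  expect_true(all(paste(out$pos1, out$res1) %in% key |
                    paste(out$pos2, out$res2) %in% key))
  expect_true(all(out$pos1 != out$pos2))
})
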
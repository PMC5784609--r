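iso_tab <- function(ranks) {
  data.table::data.table(cluster_id = names(ranks),
                         isoform_rank = unname(ranks))
}

test_that("major isoform takes the highest count, ties to the distal isoform", {
  usage <- data.table::data.table(
    gene_id = "g1", cluster_id = c("p", "d"), sample_id = "S1",
    count = c(70L, 30L))
  iso <- iso_tab(c(p = 1L, d = 2L))
  expect_identical(major_isoform(usage, iso)$cluster_id, "p")
  usage$count <- c(50L, 50L)
  expect_identical(major_isoform(usage, iso)$cluster_id, "d")
  single <- usage[1]
  expect_identical(major_isoform(single, iso)$cluster_id, "p")
})

test_that("the exact isoform-vs-rest test reproduces the worked table", {
  counts <- data.table::data.table(
    gene_id = "g1", cluster_id = c("i1", "i2"),
    n_a = c(8L, 2L), n_b = c(2L, 8L))
  res <- suppressMessages(test_switch(counts, min_test_reads = 5L))
  expect_equal(res$p_value[1], 4252 / 184756, tolerance = 1e-10)
  # complete switch is overwhelmingly significant
  comp <- data.table::data.table(gene_id = "g1", cluster_id = c("i1", "i2"),
                                 n_a = c(100L, 0L), n_b = c(0L, 100L))
  res <- test_switch(comp)
  expect_lt(res$p_value[1], 1e-20)
  expect_true(all(res$significant))
  # identical usage proportions -> p = 1
  flat <- data.table::data.table(gene_id = "g1", cluster_id = c("i1", "i2"),
                                 n_a = c(50L, 50L), n_b = c(50L, 50L))
  expect_equal(test_switch(flat)$p_value, c(1, 1))
})

test_that("p-values match exhaustive hypergeometric enumeration", {
  set.seed(77)
  for (i in 1:100) {
    tot <- sample(10:60, 1)
    a <- rbinom(1, tot, 0.5); b <- tot - a
    tot2 <- sample(10:60, 1)
    c <- rbinom(1, tot2, 0.3); d <- tot2 - c
    counts <- data.table::data.table(
      gene_id = "g", cluster_id = c("i1", "i2"),
      n_a = c(a, b), n_b = c(c, d))
    res <- suppressMessages(test_switch(counts, min_test_reads = 1L))
    expect_equal(res$p_value[1], oracle_fisher2(a, c, b, d),
                 tolerance = 1e-9)
  }
})

test_that("the test is symmetric in condition labels and BH keeps q >= p", {
  set.seed(3)
  counts <- data.table::rbindlist(lapply(1:30, function(g) {
    data.table::data.table(
      gene_id = sprintf("g%02d", g), cluster_id = c("i1", "i2"),
      n_a = as.integer(rmultinom(1, 60, c(.6, .4))),
      n_b = as.integer(rmultinom(1, 60, c(.4, .6))))
  }))
  res <- test_switch(counts)
  swapped <- data.table::copy(counts)
  data.table::setnames(swapped, c("n_a", "n_b"), c("n_b", "n_a"))
  res2 <- test_switch(swapped)
  expect_equal(res$p_value, res2$p_value)
  expect_true(all(res$q_value >= res$p_value - 1e-12))
  # BH is monotone: sorting by p sorts q
  o <- order(res$p_value)
  expect_true(all(diff(res$q_value[o]) >= -1e-12))
})

test_that("genes below the coverage gate or with one isoform are skipped", {
  counts <- data.table::data.table(
    gene_id = c("low", "low", "single"),
    cluster_id = c("i1", "i2", "i1"),
    n_a = c(5L, 5L, 100L), n_b = c(5L, 5L, 100L))
  expect_message(res <- test_switch(counts, min_test_reads = 20L),
                 "skipped 2")
  expect_identical(nrow(res), 0L)
})

test_that("the switch catalog separates major switches from usage changes", {
  res <- data.table::data.table(
    gene_id = c("sw", "sw", "usage", "usage"),
    cluster_id = c("p", "d", "p", "d"),
    frac_a = c(0.8, 0.2, 0.6, 0.4),
    frac_b = c(0.2, 0.8, 0.55, 0.45),
    q_value = c(0.01, 0.01, 0.02, 0.02),
    isoform_rank = c(1L, 2L, 1L, 2L))
  cat <- switch_catalog(res, 0.05)
  expect_identical(cat$catalog[gene_id == "sw", major_switch], TRUE)
  expect_identical(cat$catalog[gene_id == "sw", direction], "distal_shift")
  expect_identical(cat$catalog[gene_id == "usage", major_switch], FALSE)
  expect_true(is.na(cat$catalog[gene_id == "usage", direction]))
  expect_identical(cat$summary$n_major_switches, 1L)
  # non-significant genes stay out of the catalog
  res$q_value <- 0.2
  expect_identical(nrow(switch_catalog(res, 0.05)$catalog), 0L)
})

test_that("proximal gains in condition B are labelled proximal shifts", {
  counts <- data.table::data.table(
    gene_id = "g1", cluster_id = c("p", "d"),
    n_a = c(20L, 80L), n_b = c(80L, 20L))
  iso <- iso_tab(c(p = 1L, d = 2L))
  res <- test_switch(counts, isoforms = iso)
  expect_identical(res[cluster_id == "p", direction], "proximal_shift")
  expect_identical(res[cluster_id == "d", direction], "proximal_shift")
})

test_that("3'UTR length summaries honour exclusion rules", {
  iso <- data.table::data.table(
    cluster_id = c("a", "b", "c"), apa_class = "tandem",
    utr_length = c(10L, 100L, 200L))
  usage <- data.table::data.table(
    gene_id = c("gA", "gB", "gC"), cluster_id = c("a", "b", "c"),
    sample_id = "S1", count = c(1000L, 10L, 5L))
  st <- utr_length_stats(usage, iso)
  expect_identical(st$n, 3L)
  expect_equal(st$median, 100)
  # dropping the top-expressed third leaves lengths {100, 200}
  st <- utr_length_stats(usage, iso, exclude_top_frac = 1 / 3)
  expect_identical(st$n, 2L)
  expect_equal(st$median, 150)
  # gene exclusion list
  st <- utr_length_stats(usage, iso, exclude_genes = c("gA", "gB"))
  expect_equal(st$median, 200)
  # empty set after exclusion is explicit, not an error
  st <- utr_length_stats(usage, iso,
                         exclude_genes = c("gA", "gB", "gC"))
  expect_identical(nrow(st), 0L)
  one <- utr_length_stats(usage[2], iso)
  expect_equal(one$median, 100)
})
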
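test_that("equivalence-class tables parse into incidence structures", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("r1\tg1:M"), tf)
  inc <- read_ec_table(tf)
  expect_equal(dim(inc), c(1L, 1L))
  expect_equal(inc$targets$gene, "g1")
  expect_equal(inc$targets$allele, "M")

  writeLines(c("r1\tg1:M,g1:P"), tf)
  inc <- read_ec_table(tf)
  expect_equal(dim(inc), c(1L, 2L))
  expect_equal(sort(inc$targets$allele), c("M", "P"))
  expect_equal(unique(inc$targets$gene), "g1")

  writeLines(c("r1\tg1:Q"), tf)
  expect_error(read_ec_table(tf), "unparseable|allele")
  writeLines(character(), tf)
  expect_warning(inc <- read_ec_table(tf), "empty")
  expect_equal(dim(inc), c(0L, 0L))
})

test_that("reads are classified into the four ambiguity categories", {
  inc <- inc_from_sets(list(
    "g1:M",                          # unique
    c("g1:M", "g1:P"),               # allelic multi
    c("g1:M", "g2:M"),               # genomic multi
    c("g1:M", "g1:P", "g2:M")))      # complex multi
  cls <- classify_reads(inc)
  expect_equal(as.character(cls$category),
               c("unique", "allelic_multi", "genomic_multi",
                 "complex_multi"))
  expect_equal(sum(cls$fractions), 1)
  expect_equal(length(cls$category), nrow(inc$membership))
})

test_that("category fractions recover the generator's configured mixture", {
  truth <- simulate_counts(sim_config(n_genes = 20, n_cells = 4,
                                      depth_mean = 60), seed = 5)
  incs <- simulate_incidence(truth, seed = 6)
  cats <- unlist(lapply(incs, function(i) {
    cls <- classify_reads(i)
    expect_equal(as.character(cls$category),
                 as.character(attr(i, "category")))
    as.character(cls$category)
  }))
  frac <- table(factor(cats, c("unique", "genomic_multi", "allelic_multi",
                               "complex_multi"))) / length(cats)
  mix <- truth$config$read_mix[c("unique", "genomic", "allelic", "complex")]
  se <- sqrt(mix * (1 - mix) / length(cats))
  expect_true(all(abs(as.numeric(frac) - mix) < 5 * se + 1e-3))
})

test_that("unique-reads counting discards all multi-reads", {
  inc <- inc_from_sets(c(rep(list("g1:M"), 3), list("g1:P"),
                         list(c("g1:M", "g1:P"))))
  u <- unique_read_counts(inc)
  expect_equal(unname(u$x[1, 1]), 3)
  expect_equal(unname(u$y[1, 1]), 1)

  allmulti <- inc_from_sets(list(c("g1:M", "g1:P"), c("g1:M", "g2:M")))
  u2 <- unique_read_counts(allmulti)
  expect_true(all(u2$n == 0))
})

test_that("weighted allocation reaches the closed-form fixed point", {
  inc <- inc_from_sets(c(rep(list("g1:M"), 3), list("g1:P"),
                         list(c("g1:M", "g1:P"))))
  wa <- weighted_allocation_em(inc)
  # fixed point of m = 3 + m/5 with m + p = 5
  expect_equal(unname(wa$x[1, 1]), 3.75, tolerance = 1e-6)
  expect_equal(unname(wa$y[1, 1]), 1.25, tolerance = 1e-6)
  expect_true(attr(wa, "converged"))

  lone <- weighted_allocation_em(inc_from_sets(list(c("g1:M", "g1:P"))))
  expect_equal(unname(lone$x[1, 1]), 0.5)
  expect_equal(unname(lone$y[1, 1]), 0.5)

  uniq <- inc_from_sets(list("g1:M", "g1:M", "g2:P"))
  expect_equal(weighted_allocation_em(uniq)$x,
               unique_read_counts(uniq)$x)
  expect_equal(weighted_allocation_em(uniq)$y,
               unique_read_counts(uniq)$y)
})

test_that("every EM iterate conserves reads and the log-likelihood is monotone", {
  set.seed(31)
  truth <- simulate_counts(sim_config(n_genes = 6, n_cells = 1,
                                      depth_mean = 30), seed = 31)
  inc <- simulate_incidence(truth, seed = 32)[[1]]
  n_reads <- nrow(inc$membership)
  for (k in c(1L, 2L, 5L, 50L)) {
    wa <- suppressWarnings(weighted_allocation_em(inc, max_iter = k))
    expect_equal(sum(wa$n), n_reads, tolerance = 1e-9)
  }
  wa <- weighted_allocation_em(inc)
  expect_true(all(diff(attr(wa, "loglik")) > -1e-9))
})

test_that("the EM fixed point matches brute-force iteration on small incidences", {
  set.seed(99)
  for (rep in 1:20) {
    n_reads <- sample(2:10, 1)
    sets <- lapply(seq_len(n_reads), function(i) {
      k <- sample(1:3, 1)
      sample(c("g1:M", "g1:P", "g2:M", "g2:P"), k)
    })
    inc <- inc_from_sets(sets)
    wa <- suppressWarnings(
      weighted_allocation_em(inc, tol = 1e-12, max_iter = 50000L))
    oracle <- em_oracle(inc)
    want <- tapply(oracle, paste(inc$targets$allele, inc$targets$gene),
                   sum)
    at <- function(tbl, key) if (key %in% names(tbl)) unname(tbl[[key]]) else 0
    for (g in rownames(wa$x)) {
      expect_equal(unname(wa$x[g, 1]), at(want, paste("M", g)),
                   tolerance = 1e-6)
      expect_equal(unname(wa$y[g, 1]), at(want, paste("P", g)),
                   tolerance = 1e-6)
    }
  }
})

test_that("synthetic SAM files round-trip through read_alignments", {
  truth <- simulate_counts(sim_config(n_genes = 5, n_cells = 1,
                                      depth_mean = 15), seed = 21)
  inc <- simulate_incidence(truth, seed = 22)[[1]]
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(inc, sam)
  back <- read_alignments(sam, cell = inc$cell)
  key <- function(i) {
    tl <- paste0(i$targets$gene, ":", i$targets$allele)
    sets <- apply(as.matrix(i$membership), 1, function(r)
      paste(sort(tl[r > 0]), collapse = ","))
    sort(paste(i$reads, sets))
  }
  expect_equal(key(back), key(inc))
  expect_equal(unique_read_counts(back, genes = rownames(truth$counts$x))$x,
               unique_read_counts(inc, genes = rownames(truth$counts$x))$x)
})

test_that("malformed reference names in alignments are a hard error", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               "@SQ\tSN:g1_Q\tLN:1000",
               "r1\t0\tg1_Q\t1\t255\t10M\t*\t0\t0\tACGTACGTAC\t*"), sam)
  expect_error(read_alignments(sam), "g1_Q")
})
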
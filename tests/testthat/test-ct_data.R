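test_that("write -> read round-trips wide and long layouts exactly", {
  set.seed(42)
  ct <- array(20 + rnorm(3 * 4 * 2, sd = 0.5), dim = c(3, 4, 2))
  m <- ct_matrix(ct, c("gA", "gB", "gC"), paste0("s", 1:4))
  for (fmt in c("wide", "long")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_ct_table(m, path, format = fmt)
    m2 <- read_ct_table(path)
    expect_identical(m2$genes, m$genes)
    expect_identical(m2$samples, m$samples)
    expect_equal(m2$ct, m$ct, tolerance = 1e-12)
  }
})

test_that("declared dimensions survive reading (11 x 23 x 4 design)", {
  d <- generate_ct_dataset(synthetic_config(), seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ct_table(d$ct, path, format = "long")
  m <- read_ct_table(path)
  expect_equal(dim(m), c(11L, 23L, 4L))
  expect_identical(m$groups, d$ct$groups)
})

test_that("NA cells are kept as missing, never dropped", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,s1_1,s1_2,s2_1,s2_2",
               "g1,20.1,NA,21.0,20.9",
               "g2,18.0,18.2,18.1,18.0"), path)
  m <- read_ct_table(path)
  expect_equal(dim(m), c(2L, 2L, 2L))
  expect_equal(n_missing(m), 1L)
  expect_true(is.na(m$ct["g1", "s1", 2]))
})

test_that("malformed input produces informative parse errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,s1,s2", "g1,20.1,abc"), path)
  expect_error(read_ct_table(path), "non-numeric Ct cell.*s2")
  writeLines(c("gene,s1,s2", "g1,20.1,21", "g1,19,19"), path)
  expect_error(read_ct_table(path), "duplicate gene id")
  writeLines(c("nogene,s1", "x,20"), path)
  expect_error(read_ct_table(path), "gene")
  expect_error(read_ct_table(withr::local_tempfile()), "not found")
})

test_that("collapse_replicates averages non-missing wells per rule", {
  m <- ct_matrix(array(c(20, 20.4), dim = c(1, 1, 2)), "g", "s")
  expect_equal(collapse_replicates(m, "mean")$ct[1, 1, 1], 20.2)
  m4 <- ct_matrix(array(c(19.8, 20.0, 20.2, 25.0), dim = c(1, 1, 4)), "g", "s")
  expect_equal(collapse_replicates(m4, "median")$ct[1, 1, 1], 20.1)
  expect_equal(collapse_replicates(
    ct_matrix(array(20, dim = c(1, 1, 4)), "g", "s"), "mean")$ct[1, 1, 1], 20)
  # a fully missing well stays missing and is reported
  ct <- array(c(20, NA, NA, NA), dim = c(2, 1, 2))
  mm <- ct_matrix(ct, c("g1", "g2"), "s1")
  expect_warning(cc <- collapse_replicates(mm), "g2/s1")
  expect_true(is.na(cc$ct["g2", "s1", 1]))
  expect_equal(cc$ct["g1", "s1", 1], 20)
})

test_that("subset_samples projects columns and validates membership", {
  d <- generate_ct_dataset(synthetic_config(), seed = 5)
  m <- d$ct
  all_spec <- subset_spec("everything", m$samples)
  expect_equal(subset_samples(m, all_spec)$ct, m$ct)
  five <- subset_spec("five", m$samples[c(3, 1, 9, 20, 11)])
  sub <- subset_samples(m, five)
  expect_equal(dim(sub), c(11L, 5L, 4L))
  expect_identical(sub$samples, five$samples)  # order follows the spec
  expect_identical(sub$genes, m$genes)
  expect_error(subset_samples(m, subset_spec("bad", "Fr9")), "Fr9")
})

test_that("collapse and subset commute", {
  d <- generate_ct_dataset(synthetic_config(), seed = 11)
  spec <- subset_spec("fruit", paste0("Fr", 1:5))
  a <- subset_samples(collapse_replicates(d$ct), spec)
  b <- collapse_replicates(subset_samples(d$ct, spec))
  expect_equal(a$ct, b$ct, tolerance = 1e-14)
})

test_that("expression summary matches per-gene quantile oracle and is
           sample-order invariant", {
  d <- generate_ct_dataset(synthetic_config(), seed = 13)
  m <- collapse_replicates(d$ct)
  s <- summarize_expression(m)
  expect_true(all(s$min <= s$q1 & s$q1 <= s$median &
                    s$median <= s$q3 & s$q3 <= s$max))
  for (g in sample(m$genes, 4)) {
    v <- m$ct[g, , 1]
    row <- s[s$gene == g, ]
    expect_equal(row$median, median(v))
    expect_equal(row$q1, unname(quantile(v, 0.25)))
    expect_equal(c(row$min, row$max), range(v))
  }
  perm <- sample(m$samples)
  s2 <- summarize_expression(subset_samples(m, subset_spec("p", perm)))
  expect_equal(s2[order(s2$gene), ], s[order(s$gene), ], ignore_attr = TRUE)
})

test_that("summary degenerate cases", {
  m <- ct_matrix(matrix(20, 1, 5), "flat", paste0("s", 1:5))
  s <- summarize_expression(m)
  expect_equal(unlist(s[1, c("min", "q1", "median", "q3", "max")]),
               rep(20, 5), ignore_attr = TRUE)
  m2 <- ct_matrix(matrix(18:22, 1), "g", paste0("s", 1:5))
  s2 <- summarize_expression(m2)
  expect_equal(s2$median, 20)
  expect_equal(c(s2$min, s2$max), c(18, 22))
})

test_that("ct_matrix enforces its invariants", {
  expect_error(ct_matrix(matrix(-1, 1, 1), "g", "s"), "finite and > 0")
  expect_error(ct_matrix(matrix(1, 2, 2), c("g", "g"), c("a", "b")),
               "duplicate gene")
  expect_error(ct_matrix(matrix(1, 2, 2), c("g1", "g2"), c("a", "a")),
               "duplicate sample")
  expect_error(ct_matrix(matrix(1, 2, 2), "g1", c("a", "b")), "2 x 2")
})
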
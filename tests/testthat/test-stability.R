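test_that("relative quantities follow the min-Ct efficiency transform", {
  m <- ct_matrix(matrix(c(20, 21, 22), 1), "g", c("a", "b", "c"))
  expect_equal(unname(to_relative_quantity(m)$q[1, ]), c(1, 0.5, 0.25))
  flat <- ct_matrix(matrix(20, 1, 4), "g", paste0("s", 1:4))
  expect_equal(unname(to_relative_quantity(flat)$q[1, ]), rep(1, 4))
  m2 <- ct_matrix(matrix(c(20, 21), 1), "g", c("a", "b"))
  q <- to_relative_quantity(m2, 1.93)
  expect_equal(unname(q$q[1, 2]), 1 / 1.93, tolerance = 1e-12)
  # per-gene max exactly 1
  d <- generate_ct_dataset(synthetic_config(), seed = 2)
  qq <- to_relative_quantity(collapse_replicates(d$ct))
  expect_equal(unname(apply(qq$q, 1, max)), rep(1, 11))
  expect_error(to_relative_quantity(m2, 0.9), "> 1")
})

test_that("delta-Ct stability: constant offsets and sample effects cancel", {
  s <- 6
  base <- 20 + rnorm(s)
  m <- ct_matrix(rbind(base, base + 3), c("g1", "g2"), paste0("s", 1:s))
  st <- deltact_stability(m)
  expect_equal(st$value, c(0, 0))
  # adding a per-sample constant to every gene changes nothing
  m3 <- rand_ct(4, 6, seed = 101)
  shift <- rnorm(6, sd = 2)
  m3s <- ct_matrix(sweep(m3$ct[, , 1], 2, -shift), m3$genes, m3$samples)
  expect_equal(deltact_stability(m3)$value, deltact_stability(m3s)$value,
               tolerance = 1e-12)
  expect_error(deltact_stability(ct_matrix(matrix(20, 1, 3), "g",
                                           c("a", "b", "c"))), "2 genes")
})

test_that("delta-Ct matches exhaustive pair-enumeration oracle", {
  for (seed in 1:10) {
    m <- rand_ct(sample(2:6, 1), sample(3:10, 1), seed = 200 + seed)
    st <- deltact_stability(m)
    expect_equal(setNames(st$value, st$gene), oracle_deltact(m$ct[, , 1]),
                 tolerance = 1e-12)
  }
})

test_that("geNorm M: single pair and proportional genes", {
  m <- rand_ct(2, 8, seed = 7)
  q <- quantity_of(m)
  mv <- genorm_m_values(q)
  expect_equal(unname(mv[1]), unname(mv[2]))
  expect_equal(unname(mv[1]), sd(log2(q$q[1, ] / q$q[2, ])))
  # proportional genes have zero pairwise variation
  base <- 2^rnorm(6)
  qm <- structure(list(q = rbind(g1 = base, g2 = 0.3 * base,
                                 g3 = 2^rnorm(6)),
                       genes = c("g1", "g2", "g3"),
                       samples = paste0("s", 1:6), groups = NULL,
                       efficiencies = c(g1 = 2, g2 = 2, g3 = 2)),
                  class = "quantity_matrix")
  mv3 <- genorm_m_values(qm)
  expect_lt(abs(sd(log2(qm$q[1, ] / qm$q[2, ]))), 1e-12)
  expect_equal(unname(mv3["g1"]),
               mean(c(0, sd(log2(qm$q[1, ] / qm$q[3, ])))), tolerance = 1e-10)
})

test_that("geNorm M matches brute-force oracle on random tables", {
  for (seed in 1:10) {
    m <- rand_ct(sample(3:6, 1), sample(4:10, 1), seed = 300 + seed)
    q <- quantity_of(m)
    expect_equal(genorm_m_values(q), oracle_genorm_m(q$q), tolerance = 1e-12)
  }
})

test_that("geNorm M equals delta-Ct stability at efficiency 2", {
  for (seed in 1:5) {
    m <- rand_ct(5, 8, seed = 400 + seed)
    expect_equal(unname(genorm_m_values(quantity_of(m))),
                 deltact_stability(m)$value, tolerance = 1e-12)
  }
})

test_that("geNorm elimination matches stepwise recomputation oracle", {
  for (seed in 1:6) {
    m <- rand_ct(6, 9, seed = 500 + seed)
    q <- quantity_of(m)
    rk <- genorm_ranking(q)
    orc <- oracle_genorm_elimination(q$q)
    # dropped order: ranks n, n-1, ..., 3
    dropped <- rk$gene[match(length(q$genes):3, rk$rank)]
    expect_identical(dropped, orc$order_dropped)
    expect_setequal(rk$gene[rk$rank == 1L], orc$survivors)
  }
})

test_that("geNorm final pair shares rank 1, next gene gets rank 3", {
  m <- rand_ct(5, 10, seed = 77)
  rk <- genorm_ranking(quantity_of(m))
  expect_equal(sort(rk$rank), c(1L, 1L, 3L, 4L, 5L))
  # a clearly noisy gene is eliminated first
  set.seed(8)
  base <- 2^rnorm(8)
  q <- structure(list(q = rbind(a = base / max(base), b = base / max(base),
                                c = base / max(base),
                                d = 2^(rnorm(8, sd = 2))),
                      genes = letters[1:4], samples = paste0("s", 1:8),
                      groups = NULL, efficiencies = setNames(rep(2, 4),
                                                             letters[1:4])),
                 class = "quantity_matrix")
  rk2 <- genorm_ranking(q)
  expect_equal(rk2$rank[rk2$gene == "d"], 4L)
  expect_gt(rk2$value[rk2$gene == "d"], max(rk2$value[rk2$gene != "d"]))
  expect_error(genorm_ranking(quantity_of(rand_ct(2, 5, seed = 1))),
               ">= 3 genes")
})

test_that("pairwise variation V(n/n+1) matches direct recomputation and is
           sample-permutation invariant", {
  m <- rand_ct(6, 10, seed = 91)
  q <- quantity_of(m)
  rk <- genorm_ranking(q)
  v <- genorm_pairwise_variation(q, rk)
  ord <- rk$gene[order(rk$rank, match(rk$gene, q$genes))]
  for (i in seq_len(nrow(v))) {
    n <- v$n[i]
    nf_n <- apply(q$q[ord[1:n], , drop = FALSE], 2, geomean)
    nf_n1 <- apply(q$q[ord[1:(n + 1)], , drop = FALSE], 2, geomean)
    expect_equal(v$v[i], sd(log2(nf_n / nf_n1)), tolerance = 1e-12)
  }
  perm <- sample(ncol(q$q))
  q2 <- q; q2$q <- q$q[, perm]; q2$samples <- q$samples[perm]
  expect_equal(genorm_pairwise_variation(q2, rk)$v, v$v, tolerance = 1e-12)
  # adding a gene proportional to NF_n leaves the factor unchanged
  nf2 <- apply(q$q[ord[1:2], , drop = FALSE], 2, geomean)
  q3 <- q
  q3$q <- rbind(q$q[ord[1:2], ], extra = nf2 / max(nf2))
  q3$genes <- rownames(q3$q) <- c(ord[1:2], "extra")
  q3$efficiencies <- setNames(rep(2, 3), q3$genes)
  # pin the order so "extra" is the (n+1)-th gene
  rk3 <- structure(data.frame(gene = q3$genes, value = c(0, 0, 1),
                              rank = c(1L, 1L, 3L)),
                   method = "genorm", subset = "all",
                   class = c("stability_table", "data.frame"))
  v3 <- genorm_pairwise_variation(q3, rk3)
  expect_equal(v3$v[1], 0, tolerance = 1e-12)
  expect_error(genorm_pairwise_variation(q, rk, max_n = 6), "smaller")
})

test_that("NormFinder: pure sample effects give zero SVs; per-sample shifts
           cancel", {
  set.seed(21)
  load <- rnorm(8, sd = 1.5)
  ct <- outer(c(18, 20, 22, 24), rep(1, 8)) + rep(load, each = 4)
  m <- ct_matrix(ct, paste0("g", 1:4), paste0("s", 1:8))
  sv <- normfinder_stability(quantity_of(m))
  expect_equal(sv$value, rep(0, 4), tolerance = 1e-10)
  m2 <- rand_ct(5, 10, seed = 22)
  shift <- rnorm(10, sd = 3)
  m2s <- ct_matrix(sweep(m2$ct[, , 1], 2, -shift), m2$genes, m2$samples)
  expect_equal(normfinder_stability(quantity_of(m2))$value,
               normfinder_stability(quantity_of(m2s))$value,
               tolerance = 1e-10)
  expect_error(normfinder_stability(quantity_of(rand_ct(2, 5, seed = 1))),
               "3 genes")
})

test_that("NormFinder matches the direct variance-decomposition oracle", {
  for (seed in 1:8) {
    m <- rand_ct(sample(3:6, 1), sample(4:10, 1), seed = 600 + seed)
    q <- quantity_of(m)
    sv <- normfinder_stability(q)
    expect_equal(setNames(sv$value, sv$gene), oracle_normfinder(q$q),
                 tolerance = 1e-12)
  }
  # grouped variant, 2 groups of 5
  m <- rand_ct(5, 10, seed = 999)
  q <- quantity_of(m)
  groups <- setNames(rep(c("A", "B"), each = 5), m$samples)
  svg <- normfinder_stability(q, groups = groups)
  expect_equal(setNames(svg$value, svg$gene),
               oracle_normfinder_grouped(q$q, unname(groups[m$samples])),
               tolerance = 1e-12)
  # grouping changes the statistic in general
  sv0 <- normfinder_stability(q)
  expect_false(isTRUE(all.equal(svg$value, sv0$value)))
  expect_error(normfinder_stability(q, groups = setNames(
    c("A", rep("B", 9)), m$samples)), "singleton")
})

test_that("BestKeeper statistics match per-formula recomputation", {
  for (seed in 1:6) {
    m <- rand_ct(6, 8, seed = 700 + seed)
    bk <- bestkeeper_stats(m)
    orc <- oracle_bestkeeper(m$ct[, , 1])
    expect_equal(bk$per_gene$sd_ct, orc$per_gene$sd_ct, tolerance = 1e-10)
    expect_equal(bk$per_gene$cv_pct, orc$per_gene$cv_pct, tolerance = 1e-10)
    expect_equal(bk$per_gene$geo_mean_ct, orc$per_gene$geo_mean_ct,
                 tolerance = 1e-10)
    expect_equal(unname(bk$index), orc$index, tolerance = 1e-10)
    expect_equal(bk$per_gene$r_vs_index, orc$per_gene$r, tolerance = 1e-10)
  }
})

test_that("BestKeeper location/scale behavior and degenerate correlation", {
  m <- rand_ct(3, 8, seed = 31)
  bk <- bestkeeper_stats(m)
  shifted <- m$ct[, , 1]; shifted[2, ] <- shifted[2, ] + 5
  bk2 <- bestkeeper_stats(ct_matrix(shifted, m$genes, m$samples))
  expect_equal(bk2$per_gene$sd_ct[2], bk$per_gene$sd_ct[2], tolerance = 1e-12)
  expect_lt(bk2$per_gene$cv_pct[2], bk$per_gene$cv_pct[2])
  expect_gt(bk2$per_gene$geo_mean_ct[2], bk$per_gene$geo_mean_ct[2])
  ct <- rbind(flat = rep(20, 6), g2 = 20 + rnorm(6))
  expect_warning(bkf <- bestkeeper_stats(
    ct_matrix(ct, c("flat", "g2"), paste0("s", 1:6))), "flat")
  expect_true(is.na(bkf$per_gene$r_vs_index[1]))
  expect_equal(bkf$per_gene$sd_ct[1], 0)
})

test_that("BestKeeper ranking by SD vs CV can legitimately differ", {
  bk <- bestkeeper_stats(rand_ct(3, 8, seed = 41))
  expect_equal(bestkeeper_ranking(bk)$rank,
               unname(competition_ranks(setNames(bk$per_gene$sd_ct,
                                                 bk$per_gene$gene))))
  # equal SD, unequal mean: SD ties, CV discriminates
  s <- c(-1, 0, 1, 0, -1, 1)
  ct <- rbind(low = 15 + s, high = 30 + s, other = 20 + 0.5 * s)
  m <- ct_matrix(ct, rownames(ct), paste0("s", 1:6))
  bk2 <- bestkeeper_stats(m)
  by_sd <- bestkeeper_ranking(bk2)
  by_cv <- bestkeeper_ranking(bk2, criterion = "cv")
  expect_equal(by_sd$rank[1:2], c(2L, 2L))  # tie under SD
  expect_false(identical(by_sd$rank, by_cv$rank))
  expect_lt(by_cv$value[by_cv$gene == "high"],
            by_cv$value[by_cv$gene == "low"])
})

test_that("all four methods hit their floor on noise-free proportional
           genes, and only BestKeeper SD sees loading effects", {
  set.seed(51)
  load <- rnorm(10, sd = 1)
  ct <- outer(seq(18, 24, length.out = 5), rep(1, 10)) + rep(load, each = 5)
  m <- ct_matrix(ct, paste0("g", 1:5), paste0("s", 1:10))
  q <- quantity_of(m)
  expect_equal(deltact_stability(m)$value, rep(0, 5), tolerance = 1e-10)
  expect_equal(unname(genorm_m_values(q)), rep(0, 5), tolerance = 1e-10)
  expect_equal(normfinder_stability(q)$value, rep(0, 5), tolerance = 1e-10)
  bk <- bestkeeper_stats(m)
  expect_equal(bk$per_gene$sd_ct, rep(sd(load), 5), tolerance = 1e-10)
  # same genes, loading removed: BestKeeper SD drops to zero
  m0 <- ct_matrix(outer(seq(18, 24, length.out = 5), rep(1, 10)),
                  paste0("g", 1:5), paste0("s", 1:10))
  expect_warning(bk0 <- bestkeeper_stats(m0), "undefined")
  expect_equal(bk0$per_gene$sd_ct, rep(0, 5))
})
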
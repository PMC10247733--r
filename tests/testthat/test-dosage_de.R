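test_that("top-5 ERCC normalization follows its defining arithmetic", {
  tab <- rbind(gene1 = c(50, 200),
               matrix(rep(c(100, 400), each = 6), 6, 2, byrow = FALSE,
                      dimnames = list(sprintf("ERCC-%d", 1:6), NULL)))
  tab["ERCC-6", ] <- c(1, 4)   # lowest-mean spike-in, excluded from top 5
  colnames(tab) <- c("s1", "s2")
  norm <- ercc_normalize(tab)
  expect_equal(unname(norm["gene1", "s1"]), 0.5)
  expect_equal(unname(norm["gene1", "s2"]), 0.5)

  # identical spike-ins across samples leave between-sample ratios intact
  tab2 <- rbind(gene1 = c(10, 30),
                matrix(100, 5, 2,
                       dimnames = list(sprintf("ERCC-%d", 1:5), NULL)))
  n2 <- ercc_normalize(tab2)
  expect_equal(unname(n2["gene1", 2] / n2["gene1", 1]), 3)

  expect_error(ercc_normalize(tab2[1:4, ]), "normalization error")
  tab3 <- tab2; tab3[2:6, 1] <- 0
  expect_error(ercc_normalize(tab3), "normalization error")
})

test_that("exact rank-sum p-values match small-sample enumeration", {
  # identical multisets are perfectly exchangeable
  expect_equal(wilcoxon_rank_sum(c(1, 2, 5), c(1, 2, 5)), 1)
  # fully separated triples: 2 of the 20 splits are as extreme
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1)

  set.seed(40)
  for (rep in 1:20) {
    n <- sample(2:4, 1); m <- sample(2:4, 1)
    x <- sample(1:6, n, replace = TRUE)   # ties on purpose
    y <- sample(1:6, m, replace = TRUE)
    expect_equal(wilcoxon_rank_sum(x, y),
                 wilcox_permutation_oracle(x, y), tolerance = 1e-10)
  }
})

test_that("large-sample rank-sum agrees with the reference implementation", {
  set.seed(41)
  for (rep in 1:5) {
    x <- rnorm(40); y <- rnorm(35, 0.3)
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    expect_equal(wilcoxon_rank_sum(x, y), ref, tolerance = 1e-10)
  }
})

test_that("BH step-up matches its definition and the reference", {
  expect_equal(bh_correct(0.03), 0.03)
  expect_equal(bh_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_correct(rep(1, 5)), rep(1, 5))
  set.seed(42)
  for (rep in 1:10) {
    p <- runif(sample(1:50, 1))
    q <- bh_correct(p)
    expect_equal(q, bh_bruteforce(p))
    expect_equal(q, stats::p.adjust(p, "BH"))
  }
})

test_that("stage ratios recover the planted dosage and flag deviations", {
  sim <- simulate_cells(sim_config(
    n_cells_per_group = 1000, n_genes = 300, seed = 43,
    deviations = data.frame(gene = c("g0121", "g0122"), stage = "G2M",
                            log2_offset = -0.5)))
  truth <- sim$truth$cells
  counts <- as.matrix(sim$matrix$counts)
  hap <- truth$group == "haploid"
  tab <- stage_ratios(counts[hap, ], counts[!hap, ],
                      truth$true_phase[hap], truth$true_phase[!hap], "S")
  expect_lt(abs(median(tab$log2_ratio, na.rm = TRUE) - 1), 0.05)
  expect_true(all(tab$q_value >= tab$p_value - 1e-12))

  tab_g2m <- stage_ratios(counts[hap, ], counts[!hap, ],
                          truth$true_phase[hap], truth$true_phase[!hap],
                          "G2M")
  dev_rows <- tab_g2m[tab_g2m$gene %in% c("g0121", "g0122"), ]
  expect_true(all(dev_rows$log2_ratio < 0.8))

  expect_error(
    stage_ratios(counts[hap, ], counts[!hap, ],
                 rep("G1S", sum(hap)), truth$true_phase[!hap], "G2M"),
    "stage error")
})

test_that("identical populations give null-behaved stage statistics", {
  set.seed(44)
  n <- 60
  x <- matrix(rpois(n * 100, 5), n, 100,
              dimnames = list(NULL, sprintf("g%03d", 1:100)))
  y <- matrix(rpois(n * 100, 5), n, 100,
              dimnames = list(NULL, sprintf("g%03d", 1:100)))
  tab <- stage_ratios(x, y, rep("S", n), rep("S", n), "S")
  expect_lt(abs(median(tab$log2_ratio)), 0.1)
  expect_lte(sum(tab$q_value < 0.01), 2)
})

test_that("the cutoff census counts sub-cutoff genes and converts the
           cutoff to linear space", {
  tab <- data.frame(gene = sprintf("g%d", 1:6),
                    stage = rep(c("G2M", "MG1"), each = 3),
                    log2_ratio = c(1, 0.4, NA, 1, 1, 0.49),
                    stringsAsFactors = FALSE)
  cen <- cutoff_census(tab, 0.5)
  expect_equal(cen$linear_cutoff, 2^0.5)
  expect_equal(cen$linear_cutoff_rounded, 1.4)
  cc <- cen$counts
  expect_equal(cc$n_below[cc$stage == "G2M"], 1)
  expect_equal(cc$n_below[cc$stage == "MG1"], 1)
  expect_equal(cc$n_excluded_zero[cc$stage == "G2M"], 1)

  all_one <- data.frame(gene = sprintf("g%d", 1:4), stage = "S",
                        log2_ratio = rep(1, 4))
  expect_equal(cutoff_census(all_one, 0.5)$counts$n_below, 0)
})
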
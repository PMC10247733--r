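test_that("DAPI binning cuts at within-group quantiles", {
  cells <- data.frame(cell_id = sprintf("c%d", 1:10), group = "g",
                      dapi_intensity = 1:10)
  binned <- dapi_bin(cells, c(0.3, 0.7))
  expect_identical(binned$dapi_bin,
                   c(rep("low", 3), rep("medium", 4), rep("high", 3)))
  expect_identical(unname(attr(binned, "bin_stage")["high"]), "G2/M")

  flat <- data.frame(cell_id = sprintf("c%d", 1:10), group = "g",
                     dapi_intensity = rep(5, 10))
  expect_error(dapi_bin(flat), "degenerate")
  expect_error(dapi_bin(cells, c(0.7, 0.3)), "quantile")

  cfg <- sim_config(seed = 70)
  tab <- simulate_foci(cfg)
  binned2 <- dapi_bin(tab$cells)
  for (g in c("haploid", "diploid")) {
    high_frac <- mean(binned2$dapi_bin[binned2$group == g] == "high")
    expect_lt(abs(high_frac - 0.3), 0.02)  # upper 30% by construction
    # high bin is enriched for 4N-like cells
    hi <- binned2$group == g & binned2$dapi_bin == "high"
    expect_gt(mean(binned2$true_content[hi]),
              mean(binned2$true_content[binned2$group == g & !hi]))
  }
})

test_that("replicate foci ratios and the one-sample test follow the
           textbook arithmetic", {
  mk <- function(counts_per_rep) {
    cells <- do.call(rbind, lapply(seq_along(counts_per_rep), function(r)
      data.frame(cell_id = sprintf("r%d_c%d", r,
                                   seq_along(counts_per_rep[[r]])),
                 group = "g", replicate = r,
                 dapi_intensity = 1)))
    foci <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      k <- counts_per_rep[[cells$replicate[i]]][
        as.integer(sub(".*_c", "", cells$cell_id[i]))]
      if (k == 0) return(NULL)
      data.frame(cell_id = cells$cell_id[i], channel = "gH2AX",
                 x = runif(k), y = runif(k))
    }))
    structure(list(cells = cells, foci = foci), class = "FociTable")
  }
  den <- mk(list(rep(10, 5), rep(10, 5), rep(10, 5)))
  num <- mk(list(rep(10, 5), rep(11, 5), rep(9, 5)))
  res <- foci_ratio(num, den, expected_ratio = 2)
  expect_equal(res$replicate_ratios, c(1.0, 1.1, 0.9))
  # one-sample t: mean 1, sd 0.1, n 3 -> t = (1 - 2) / (0.1 / sqrt(3))
  expect_equal(res$t_statistic, -10 * sqrt(3), tolerance = 1e-9)
  expect_equal(res$t_statistic, -17.3205081, tolerance = 1e-6)
  expect_equal(res$p_value, 0.0033167587, tolerance = 1e-8)

  same <- foci_ratio(den, den, expected_ratio = 2)
  expect_equal(same$replicate_ratios, rep(1, 3))
  expect_true(is.na(same$p_value))   # zero variance -> undefined test

  zero <- mk(list(rep(0, 5), rep(0, 5), rep(0, 5)))
  expect_error(foci_ratio(num, zero), "ratio error")
  one_rep <- mk(list(rep(10, 5)))
  expect_error(foci_ratio(one_rep, one_rep), "replicates")
})

test_that("colocalization matches the all-pairs oracle and is monotone in
           radius", {
  set.seed(71)
  mkf <- function(n, cells = 3) data.frame(
    cell_id = sample(sprintf("c%d", 1:cells), n, replace = TRUE),
    x = runif(n, 0, 5), y = runif(n, 0, 5))
  A <- mkf(20); B <- mkf(20)
  for (r in c(0.3, 1)) {
    res <- colocalize(A, B, r)
    orc <- coloc_oracle(A, B, r)
    expect_equal(res$frac_a_occupied, orc$frac_a, tolerance = 1e-12)
    expect_equal(res$frac_b_occupied, orc$frac_b, tolerance = 1e-12)
  }
  r_small <- colocalize(A, B, 0.1)$frac_a_occupied
  r_big <- colocalize(A, B, 2)$frac_a_occupied
  expect_lte(r_small, r_big)

  expect_equal(colocalize(A, A, 0.5)[c("frac_a_occupied",
                                       "frac_b_occupied")],
               list(frac_a_occupied = 1, frac_b_occupied = 1))
  far_b <- A; far_b$x <- far_b$x + 100
  expect_equal(colocalize(A, far_b, 0.5)$frac_a_occupied, 0)
})

test_that("simulated occupancy converges to the configured fraction", {
  cfg <- sim_config(seed = 72)
  cfg$foci$n_cells <- 500
  cfg$foci$n_replicates <- 1
  cfg$foci$coloc_fraction <- 0.5
  tab <- simulate_foci(cfg)
  co <- colocalize(tab$foci[tab$foci$channel == "gH2AX", ],
                   tab$foci[tab$foci$channel == "RAD51", ],
                   cfg$foci$match_radius)
  se <- sqrt(0.5 * 0.5 / co$n_cells_a)
  expect_lt(abs(co$frac_a_occupied - 0.5), 2 * se + 0.02)
})

test_that("the stage-stratified report localizes a G2/M-specific
           colocalization deficit", {
  cfg <- sim_config(seed = 73)
  cfg$foci$n_cells <- 400
  cfg$foci$damage_rate <- 4
  cfg$foci$coloc_fraction <- 0.6
  cfg$foci$coloc_fraction_high <- c(haploid = 0.6, diploid = 0.2)
  tab <- simulate_foci(cfg)
  rep_tab <- stage_stratified_report(tab)
  expect_identical(rep_tab$bin, c("low", "medium", "high"))
  expect_true(all(rep_tab$n_cells > 0))
  gap <- rep_tab$frac_gH2AX_occ_haploid - rep_tab$frac_gH2AX_occ_diploid
  expect_gt(gap[3], 0.2)               # deficit visible in the high bin
  expect_lt(max(abs(gap[1:2])), 0.15)  # not elsewhere
  expect_lt(rep_tab$occ_t_p[3], 0.01)
  # diploid:haploid count ratio near the dosage expectation in every bin
  expect_true(all(abs(rep_tab$ratio - 2) < 0.6))
})
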
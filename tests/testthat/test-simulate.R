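test_that("global expression ratio tracks the dosage factor", {
  for (f in c(2, 3)) {
    cfg <- sim_config(n_cells_per_group = 800, n_genes = 500,
                      dosage_factor = f, seed = 42)
    sim <- simulate_cells(cfg)
    tot <- Matrix::rowSums(sim$matrix$counts)
    g <- sim$matrix$cell_meta$group
    ratio <- mean(tot[g == "diploid"]) / mean(tot[g == "haploid"])
    expect_lt(abs(ratio / f - 1), 0.05)
  }
})

test_that("generators are reproducible under a fixed seed and streams are
           call-specific", {
  cfg <- sim_config(n_cells_per_group = 50, n_genes = 100,
                    n_signature_genes_per_phase = 10, seed = 3)
  a <- simulate_cells(cfg)
  b <- simulate_cells(cfg)
  expect_identical(as.matrix(a$matrix$counts), as.matrix(b$matrix$counts))
  expect_identical(a$truth$cells, b$truth$cells)
  expect_identical(simulate_screen(cfg)$table, simulate_screen(cfg)$table)
  expect_identical(simulate_foci(cfg)$foci, simulate_foci(cfg)$foci)
  cfg2 <- sim_config(n_cells_per_group = 50, n_genes = 100,
                     n_signature_genes_per_phase = 10, seed = 4)
  expect_false(identical(as.matrix(a$matrix$counts),
                         as.matrix(simulate_cells(cfg2)$matrix$counts)))
})

test_that("true phase dwell proportions converge to the configured
           fractions", {
  cfg <- sim_config(n_cells_per_group = 5000, n_genes = 50,
                    n_signature_genes_per_phase = 5, seed = 11)
  sim <- simulate_cells(cfg)
  for (g in c("haploid", "diploid")) {
    cells <- sim$truth$cells[sim$truth$cells$group == g, ]
    dw <- cfg$dwell_fractions[[g]]
    for (p in cc_phases()) {
      obs <- mean(cells$true_phase == p)
      se <- sqrt(dw[p] * (1 - dw[p]) / nrow(cells))
      expect_lt(abs(obs - dw[p]), 2 * se + 1e-12)
    }
  }
  # phase label always matches the arc containing theta
  arc <- floor(sim$truth$cells$theta / (2 * pi / 5)) + 1
  expect_identical(sim$truth$cells$true_phase, cc_phases()[arc])
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(dwell_fractions = list(
    haploid = c(G1S = 0.4, S = 0.2, G2 = 0.2, G2M = 0.25, MG1 = 0.1),
    diploid = c(G1S = 0.3, S = 0.25, G2 = 0.15, G2M = 0.15, MG1 = 0.15))),
    "sum")
  expect_error(sim_config(n_genes = 0), "positive")
  expect_error(sim_config(dosage_factor = -1), "dosage_factor")
  expect_error(sim_config(dropout_rate = 1.5), "dropout")
  cfg <- sim_config(n_ercc = 0)
  expect_error(simulate_bulk(cfg), "n_ercc")
})

test_that("bulk tables carry depth factors that spike-in normalization
           removes exactly", {
  cfg <- sim_config(n_genes = 60, n_signature_genes_per_phase = 5, seed = 5)
  bulk <- simulate_bulk(cfg, depth_factors = c(1, 3),
                        sample_scales = c(1, 2))
  ercc <- bulk$table[grepl("^ERCC", rownames(bulk$table)), ]
  expect_equal(unname(ercc[, 2] / ercc[, 1]), rep(3, nrow(ercc)))
  norm <- ercc_normalize(bulk$table)
  genes <- norm[!grepl("^ERCC", rownames(norm)), ]
  expect_true(all(abs(genes[, 2] / genes[, 1] - 2) < 1e-6))
})

test_that("screen counts are flat without planted depletion and depleted
           guides carry the planted effect", {
  cfg <- sim_config(seed = 9)
  cfg$screen$n_essential <- 0
  cfg$screen$depth <- 1e6
  cfg$screen$guide_sdlog <- 0
  flat <- simulate_screen(cfg)
  lfc <- guide_log2fc(flat$table, "haploid_end", "input")
  expect_lt(max(abs(lfc$log2fc)), 0.02)

  cfg2 <- sim_config(seed = 9)
  scr <- simulate_screen(cfg2)
  lfc2 <- guide_log2fc(scr$table, "haploid_end", "input")
  ess <- lfc2$gene %in% scr$essential_genes
  expect_lt(median(lfc2$log2fc[ess]), -1.5)
  expect_gt(median(lfc2$log2fc[!ess & lfc2$gene != "control"]), -0.5)
})

test_that("focus fields respect the colocalization fraction and DNA-content
           scaling", {
  cfg <- sim_config(seed = 13)
  cfg$foci$coloc_fraction <- 1
  tab <- simulate_foci(cfg)
  co <- colocalize(tab$foci[tab$foci$channel == "gH2AX", ],
                   tab$foci[tab$foci$channel == "RAD51", ],
                   cfg$foci$match_radius)
  expect_equal(co$frac_a_occupied, 1)

  cfg$foci$coloc_fraction <- 0
  cfg$foci$rad51_background <- 1
  cfg$foci$field_size <- 500
  tab0 <- simulate_foci(cfg)
  co0 <- colocalize(tab0$foci[tab0$foci$channel == "gH2AX", ],
                    tab0$foci[tab0$foci$channel == "RAD51", ],
                    cfg$foci$match_radius)
  expect_lt(co0$frac_a_occupied, 0.01)

  # equal damage rate, 2:1 DNA content -> foci count ratio near 2
  cfg3 <- sim_config(seed = 17)
  tab3 <- simulate_foci(cfg3)
  fr <- foci_ratio(
    list(cells = tab3$cells[tab3$cells$group == "diploid", ],
         foci = tab3$foci),
    list(cells = tab3$cells[tab3$cells$group == "haploid", ],
         foci = tab3$foci))
  expect_lt(abs(fr$mean_ratio - 2), 0.2)
  expect_gt(fr$p_value, 0.05)
})
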
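test_that("founder contributions propagate and conserve mass", {
  # offspring of two founders as sole reference
  p1 <- pedigree(data.frame(id = c("A", "B", "X"), sire = c(NA, NA, "A"),
                            dam = c(NA, NA, "B"),
                            in_reference = c(FALSE, FALSE, TRUE)))
  pc <- founder_contributions(p1)
  expect_equal(unname(pc$p[c("A", "B")]), c(0.5, 0.5))
  expect_equal(sum(pc$p) + pc$residual, 1, tolerance = 1e-12)

  # grandchild of four founders
  p2 <- pedigree(data.frame(
    id = c("G1", "G2", "G3", "G4", "P1", "P2", "X"),
    sire = c(NA, NA, NA, NA, "G1", "G3", "P1"),
    dam = c(NA, NA, NA, NA, "G2", "G4", "P2"),
    in_reference = c(rep(FALSE, 6), TRUE)))
  expect_equal(unname(founder_contributions(p2)$p), rep(0.25, 4))

  expect_equal(unname(founder_contributions(make_toy("full_sib_mating"))$p),
               c(0.5, 0.5))

  # unknown parent of a non-founder feeds the phantom residual
  p3 <- pedigree(data.frame(id = c("A", "B", "C", "X"),
                            sire = c(NA, NA, "A", "C"),
                            dam = c(NA, NA, NA, "B"),
                            in_reference = c(FALSE, FALSE, FALSE, TRUE)))
  pc3 <- founder_contributions(p3)
  expect_equal(pc3$residual, 0.25)
  expect_equal(sum(pc3$p) + pc3$residual, 1, tolerance = 1e-12)

  # mass conservation on random pedigrees with erased links
  for (seed in 1:4) {
    pc <- founder_contributions(random_pedigree(seed), "reference")
    expect_equal(sum(pc$p) + pc$residual, 1, tolerance = 1e-10)
    expect_true(all(pc$p >= 0))
  }
})

test_that("effective number of founders follows 1/sum(p^2)", {
  expect_equal(effective_founders(rep(1 / 7, 7)), 7)
  expect_equal(effective_founders(c(0.75, 0.25)), 1.6)
  expect_equal(effective_founders(1), 1)
  expect_error(effective_founders(c(0, 0)))
})

test_that("gene drop recovers enumerated retention on toys", {
  # founder with a single offspring as reference: each allele survives w.p. 1/2
  p1 <- pedigree(data.frame(id = c("A", "B", "X"), sire = c(NA, NA, "A"),
                            dam = c(NA, NA, "B"),
                            in_reference = c(FALSE, FALSE, TRUE)))
  exact <- gene_drop_enumeration(p1, "X")
  expect_equal(unname(exact), c(0.5, 0.5))
  gd <- gene_drop(p1, replicates = 20000, seed = 3)
  expect_true(all(abs(gd$r - exact[names(gd$r)]) < 0.01))

  # full-sib toy: enumeration over all 2^6 transmissions
  fs <- make_toy("full_sib_mating")
  exact_fs <- gene_drop_enumeration(fs, "E")
  expect_equal(unname(exact_fs), c(7 / 16, 7 / 16))
  gd_fs <- gene_drop(fs, replicates = 20000, seed = 4)
  expect_true(all(abs(gd_fs$r - exact_fs[names(gd_fs$r)]) < 0.01))

  # founders referencing themselves retain everything
  fo <- make_toy("founders_only")
  expect_true(all(gene_drop(fo, replicates = 50, seed = 1)$r == 1))

  # determinism under a fixed seed
  g1 <- gene_drop(fs, replicates = 500, seed = 11)
  g2 <- gene_drop(fs, replicates = 500, seed = 11)
  expect_identical(g1$r, g2$r)
  expect_error(gene_drop(pedigree(data.frame(id = "A", sire = NA, dam = NA)),
                         reference = character(0)))
})

test_that("founder genome equivalent combines contributions and retention", {
  expect_equal(founder_genome_equivalent(rep(0.25, 4), rep(1, 4)),
               effective_founders(rep(0.25, 4)))
  expect_equal(founder_genome_equivalent(rep(0.1, 10), rep(0.5, 10)), 5)
  expect_error(founder_genome_equivalent(c(0.5, 0.5), c(1, 0)), "zero retention")

  # f_ge <= f_e on simulated pedigrees since r <= 1
  for (seed in 1:3) {
    ped <- random_pedigree(seed)
    pc <- founder_contributions(ped)
    gd <- gene_drop(ped, replicates = 400, seed = seed)
    expect_lte(founder_genome_equivalent(pc, gd), effective_founders(pc) + 1e-9)
  }
})

test_that("diversity identities hold for all generated inputs", {
  expect_equal(non_founder_equivalent(152, 53), 1 / (1 / 53 - 1 / 152))
  expect_identical(non_founder_equivalent(40, 40), Inf)
  expect_error(non_founder_equivalent(10, 20), "exceeds")

  set.seed(5)
  for (k in 1:25) {
    fe <- runif(1, 1, 300)
    fge <- runif(1, 0.5, fe)
    dv <- genetic_diversity(fe, fge)
    expect_equal(dv$N_enf, 1 / (1 / fge - 1 / fe), tolerance = 1e-12)
    expect_equal(dv$GD, 1 - 1 / (2 * fge), tolerance = 1e-12)
    expect_equal(dv$GD_star, 1 - 1 / (2 * fe), tolerance = 1e-12)
    expect_equal(dv$GD_star - dv$GD, 1 / (2 * dv$N_enf), tolerance = 1e-10)
    expect_equal(dv$loss_total, dv$loss_founder + dv$loss_drift,
                 tolerance = 1e-12)
  }
  # no drift loss when f_e = f_ge
  dv0 <- genetic_diversity(25, 25)
  expect_equal(dv0$loss_drift, 0)
})

test_that("exact founder partition of F conserves and splits symmetric toys", {
  d <- inbreeding_decomposition(make_toy("full_sib_mating"))
  expect_equal(d$mean_F, 0.25)
  expect_equal(sort(d$table$vf), c(50, 50))
  expect_equal(d$residual_vf, 0)

  # reference without inbreeding: undefined decomposition
  d0 <- inbreeding_decomposition(make_toy("founders_only"))
  expect_true(all(is.na(d0$table$vf)))

  # conservation per animal on random pedigrees with phantom ancestry
  for (seed in c(13, 17)) {
    ped <- random_pedigree(seed, offspring_per_year = 30)
    d <- inbreeding_decomposition(ped)
    F <- inbreeding_coefficients(ped)$F[rownames(d$F_partition)]
    expect_equal(unname(rowSums(d$F_partition)), unname(F), tolerance = 1e-10)
    if (d$mean_F > 0) {
      expect_equal(sum(d$table$vf) + d$residual_vf, 100, tolerance = 1e-8)
      expect_true(all(d$table$vf >= 0))
    }
  }
})

test_that("gene-drop decomposition agrees with the exact partition", {
  fs <- make_toy("full_sib_mating")
  ex <- inbreeding_decomposition(fs, method = "exact_recursive")
  mc <- inbreeding_decomposition(fs, method = "gene_drop",
                                 replicates = 20000, seed = 7)
  # per-founder share: MC error of a 0.125 proportion at 20k replicates
  se <- sqrt(0.125 * 0.875 / 20000)
  for (f in ex$table$founder) {
    expect_lt(abs(mc$table$F_share[mc$table$founder == f] -
                    ex$table$F_share[ex$table$founder == f]), 3 * se)
  }

  ped <- random_pedigree(19, offspring_per_year = 25)
  ex2 <- inbreeding_decomposition(ped, method = "exact_recursive")
  mc2 <- inbreeding_decomposition(ped, method = "gene_drop",
                                  replicates = 8000, seed = 8)
  for (f in ex2$table$founder) {
    p <- ex2$table$F_share[ex2$table$founder == f]
    se <- sqrt(max(p * (1 - p), 1e-6) / 8000)
    expect_lt(abs(mc2$table$F_share[mc2$table$founder == f] - p), 4 * se)
  }
})

test_that("bottleneck pedigrees concentrate vf on few founders", {
  ped <- simulate_pedigree(sim_config(
    n_founders = 30, founder_sex_ratio = 0.4, n_years = 8,
    offspring_per_year = 25, n_active_sires = 3, sire_concentration = 0.1,
    missing_parent_rate = 0, reference_fraction = 0.5, n_breeds = 1,
    seed = 23))
  d <- inbreeding_decomposition(ped)
  expect_gt(d$mean_F, 0)
  top3 <- sum(sort(d$table$vf, decreasing = TRUE)[1:3])
  equal_share <- 100 * 3 / nrow(d$table)
  expect_gt(top3, equal_share)
})
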
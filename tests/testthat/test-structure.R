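test_that("structure counts match toy pedigrees", {
  rep <- count_structure(make_toy("full_sib_mating"))
  expect_equal(rep$n_total, 5)
  expect_equal(rep$n_founders, 2)
  expect_equal(rep$n_nonfounders, 3)
  expect_equal(rep$n_fullsib_groups, 1)  # C and D share sire A, dam B
  expect_equal(rep$n_founders + rep$n_nonfounders, rep$n_total)

  expect_equal(count_structure(make_toy("chain15"))$LAP, 15)

  ped <- simulate_pedigree(sim_config(n_founders = 20, n_years = 3,
                                      offspring_per_year = 12,
                                      n_active_sires = 3,
                                      missing_parent_rate = 0, seed = 2))
  r2 <- count_structure(ped)
  expect_equal(r2$n_nonfounders_both_known, r2$n_nonfounders)
  expect_true(r2$LAP >= r2$mean_max_generations)
  expect_error(count_structure(pedigree(data.frame(id = character(0),
                                                   sire = character(0),
                                                   dam = character(0)))))
})

test_that("equivalent generations recursion matches closed forms", {
  # both parents known, nothing deeper: g_e = 1
  p1 <- pedigree(data.frame(id = c("A", "B", "X"), sire = c(NA, NA, "A"),
                            dam = c(NA, NA, "B")))
  expect_equal(unname(equivalent_generations(p1, "X")$g_e), 1.0)

  # two complete generations: g_e = 2
  p2 <- pedigree(data.frame(
    id = c("G1", "G2", "G3", "G4", "P1", "P2", "X"),
    sire = c(NA, NA, NA, NA, "G1", "G3", "P1"),
    dam = c(NA, NA, NA, NA, "G2", "G4", "P2")))
  expect_equal(unname(equivalent_generations(p2, "X")$g_e), 2.0)

  # founder: 0; exactly zero iff both parents unknown
  expect_equal(unname(equivalent_generations(p2, "G1")$g_e), 0)

  # complete pedigrees of depth 1..5: g_e equals the depth
  for (depth in 1:5) {
    # build complete binary ancestry iteratively
    rows <- data.frame(id = "X", sire = "S1", dam = "D1")
    frontier <- c("S1", "D1")
    for (d in seq_len(depth)[-1]) {
      nxt <- character(0)
      for (a in frontier) {
        rows <- rbind(rows, data.frame(id = a, sire = paste0(a, "s"),
                                       dam = paste0(a, "d")))
        nxt <- c(nxt, paste0(a, "s"), paste0(a, "d"))
      }
      frontier <- nxt
    }
    suppressMessages(ped <- pedigree(rows))
    expect_equal(unname(equivalent_generations(ped, "X")$g_e), depth)
  }
})

test_that("equivalent generations recursion equals path enumeration oracle", {
  ped <- random_pedigree(seed = 11, n_founders = 25, n_years = 4,
                         offspring_per_year = 20)
  ge <- equivalent_generations(ped, "all")$g_e
  for (i in seq_len(nrow(ped))) {
    expect_equal(unname(ge[i]), ge_path_enumeration(ped, i), tolerance = 1e-12)
  }
})

test_that("pedigree completeness counts ancestor slots", {
  # only parents known out of 5 generations: 2/62
  p1 <- pedigree(data.frame(id = c("A", "B", "X"), sire = c(NA, NA, "A"),
                            dam = c(NA, NA, "B")))
  cp <- pedigree_completeness(p1, "X", depth = 5)
  expect_equal(unname(cp$a_k), 2)
  expect_equal(unname(cp$c_p), 2 / 62, tolerance = 1e-12)
  expect_equal(unname(pedigree_completeness(p1, "A", depth = 5)$c_p), 0)

  # erasing one link weakly decreases c_p
  ped <- random_pedigree(seed = 4, missing_parent_rate = 0)
  cp_full <- pedigree_completeness(ped, "all", depth = 4)$c_p
  df <- as.data.frame(ped)
  nonf <- which(!is.na(df$sire))
  df$sire[nonf[length(nonf)]] <- NA
  suppressMessages(ped2 <- pedigree(df))
  cp_cut <- pedigree_completeness(ped2, "all", depth = 4)$c_p[names(cp_full)]
  expect_true(all(cp_cut <= cp_full + 1e-12))
})

test_that("full five complete generations give c_p = 1 with a_k = 62", {
  rows <- data.frame(id = "X", sire = "Xs", dam = "Xd")
  frontier <- c("Xs", "Xd")
  for (d in 2:5) {
    nxt <- character(0)
    for (a in frontier) {
      rows <- rbind(rows, data.frame(id = a, sire = paste0(a, "s"),
                                     dam = paste0(a, "d")))
      nxt <- c(nxt, paste0(a, "s"), paste0(a, "d"))
    }
    frontier <- nxt
  }
  suppressMessages(ped <- pedigree(rows))
  cp <- pedigree_completeness(ped, "X", depth = 5)
  expect_equal(unname(cp$a_k), 62)
  expect_equal(unname(cp$c_p), 1)
})

test_that("generation intervals split paths and pool by pair counts", {
  ped <- pedigree(data.frame(
    id = c("S", "D", "Son", "Dau", "GK"),
    sire = c(NA, NA, "S", "S", "Son"),
    dam = c(NA, NA, "D", "D", "Dau"),
    sex = c("M", "F", "M", "F", "M"),
    birth_year = c(1990L, 1992L, 2000L, 2002L, 2010L)))
  gi <- generation_intervals(ped, mode = "reproducing_offspring")
  tab <- gi$table
  expect_equal(tab$mean[tab$path == "father-son"], 10)
  expect_equal(tab$mean[tab$path == "mother-daughter"], 10)
  # only Son and Dau reproduce, so GK's rows are excluded
  expect_equal(sum(tab$N), 4)

  gi_all <- generation_intervals(ped, mode = "all_offspring")
  expect_equal(sum(gi_all$table$N), 6)

  # pooled mean = sum(N * mean) / sum(N), SE = SD/sqrt(N), on any input
  set.seed(8)
  ped2 <- random_pedigree(seed = 8)
  g2 <- generation_intervals(ped2)
  expect_equal(g2$pooled$mean,
               sum(g2$table$N * g2$table$mean) / sum(g2$table$N),
               tolerance = 1e-12)
  expect_equal(g2$table$se, g2$table$sd / sqrt(g2$table$N), tolerance = 1e-12)
  expect_true(g2$pooled$mean >= min(g2$table$mean) &&
                g2$pooled$mean <= max(g2$table$mean))

  noyr <- pedigree(data.frame(id = c("A", "B"), sire = c(NA, "A"),
                              dam = c(NA, NA)))
  expect_error(generation_intervals(noyr), "no usable")
})
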
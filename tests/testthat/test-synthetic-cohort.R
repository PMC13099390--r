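test_that("config validation rejects infeasible settings", {
  expect_error(synthetic_config(relapse_rate = 1.2), "relapse_rate")
  expect_error(synthetic_config(test_retest_r = 1), "test_retest_r")
  expect_error(synthetic_config(dropout_n = 97), "dropout_n")
  expect_error(synthetic_config(rho_hamd = 0.99), "infeasible")
})

test_that("generation is deterministic and counts match the config exactly", {
  cfg <- synthetic_config(n_patients = 20, n_controls = 10, dropout_n = 4,
                          seed = 61)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1$cohort, g2$cohort)
  expect_identical(g1$choices, g2$choices)

  co <- g1$cohort
  expect_equal(sum(co$group == "patient"), 20)
  expect_equal(sum(co$group == "control"), 10)
  expect_equal(sum(co$dropped_out), 4)
  expect_equal(sum(co$arm == "MA1-D-MA2"), round(20 * 47 / 97))
  expect_true(all(co$arm[co$group == "control"] == "none"))
  expect_true(all(is.na(co$relapsed[co$group == "control"])))
  expect_true(all(is.na(co$relapsed[co$dropped_out])))
  rel <- !is.na(co$relapsed) & co$relapsed
  expect_true(all(co$days_to_event[rel] <= cfg$followup_days))
  expect_true(all(co$days_to_event[!is.na(co$relapsed) & !co$relapsed] ==
                    cfg$followup_days))

  # byte-identical files from the same seed
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_choices(g1$choices, p1)
  write_choices(g2$choices, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("choice data follow the canonical schema for both tasks and timepoints", {
  g <- generate_cohort(synthetic_config(n_patients = 6, n_controls = 4,
                                        dropout_n = 1, seed = 62))
  ch <- g$choices
  expect_silent(validate_choices(ch))
  pat <- g$cohort$participant_id[g$cohort$group == "patient"]
  expect_setequal(unique(ch$timepoint[ch$participant_id %in% pat]),
                  c("MA1", "MA2"))
  ctl <- g$cohort$participant_id[g$cohort$group == "control"]
  expect_equal(unique(ch$timepoint[ch$participant_id %in% ctl]), "MA1")
  # every participant-timepoint has the full MCQ plus an adaptive run
  n_mcq <- with(ch[ch$task_tag == "mcq", ],
                table(participant_id, timepoint))
  expect_true(all(n_mcq[n_mcq > 0] == 27))
})

test_that("the generator hits its latent calibration targets over seeds", {
  stats <- t(vapply(1:200, function(s) {
    co <- generate_cohort(synthetic_config(seed = s),
                          choices = FALSE)$cohort
    pat <- co$group == "patient"
    sp <- ((sum(pat) - 1) * var(co$true_log_k_ma1[pat]) +
             (sum(!pat) - 1) * var(co$true_log_k_ma1[!pat])) /
      (nrow(co) - 2)
    c(d = (mean(co$true_log_k_ma1[pat]) - mean(co$true_log_k_ma1[!pat])) /
        sqrt(sp),
      rho = cor(co$true_log_k_ma1, co$hamd_ma1, method = "spearman"),
      retest = cor(co$true_log_k_ma1[pat], co$true_log_k_ma2[pat]),
      rel = mean(co$relapsed, na.rm = TRUE))
  }, numeric(4)))
  expect_equal(mean(stats[, "d"]), 0.34, tolerance = 0.05)
  expect_equal(mean(stats[, "rho"]), 0.24, tolerance = 0.08)
  expect_equal(mean(stats[, "retest"]), 0.72, tolerance = 0.05)
  expect_equal(mean(stats[, "rel"]), 0.35, tolerance = 0.05)
})

test_that("a null group effect yields nominal false-positive rates", {
  rejections <- vapply(1:200, function(s) {
    co <- generate_cohort(synthetic_config(group_effect_d = 0, seed = s),
                          choices = FALSE)$cohort
    pat <- co$group == "patient"
    t.test(co$true_log_k_ma1[pat], co$true_log_k_ma1[!pat],
           var.equal = TRUE)$p.value < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.02)
  expect_lte(mean(rejections), 0.10)
})

test_that("rating scales stay in range and carry the configured correlations", {
  defs <- delaydisc:::scale_defs()
  co <- generate_cohort(synthetic_config(seed = 63), choices = FALSE)$cohort
  for (j in seq_len(nrow(defs))) {
    v <- co[[defs$name[j]]]
    expect_true(all(v >= defs$min[j] & v <= defs$max[j]), label = defs$name[j])
  }
  expect_equal(co$ctq, co$ctq_ea + co$ctq_pa + co$ctq_sa + co$ctq_en +
                 co$ctq_pn)

  rhos <- t(vapply(1:200, function(s) {
    co <- generate_cohort(synthetic_config(seed = 300 + s),
                          choices = FALSE)$cohort
    c(pa = cor(co$true_log_k_ma1, co$ctq_pa, method = "spearman"),
      en = cor(co$true_log_k_ma1, co$ctq_en, method = "spearman"),
      erq = cor(co$true_log_k_ma1, co$erq, method = "spearman"))
  }, numeric(3)))
  expect_equal(mean(rhos[, "pa"]), 0.18, tolerance = 0.08)
  expect_equal(mean(rhos[, "en"]), 0.16, tolerance = 0.08)
  expect_lt(abs(mean(rhos[, "erq"])), 0.05)

  # zero-correlation configuration: all nuisance scales near zero at one seed
  co0 <- generate_cohort(synthetic_config(rho_ctq_pa = 0, rho_ctq_en = 0,
                                          seed = 64),
                         choices = FALSE)$cohort
  for (nm in c("erq", "bscs", "swls", "ctq_pa", "ctq_en", "tleq")) {
    expect_lt(abs(cor(co0$true_log_k_ma1, co0[[nm]], method = "spearman")),
              0.17)
  }
})
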
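ct_table <- function(genes, wt_ct, mut_ct, ref_ct = 10, reps = 1) {
  rows <- do.call(rbind, lapply(seq_along(genes), function(i) {
    data.frame(gene = genes[i],
               strain = rep(c("wild-type", "mutant"), each = reps),
               replicate = rep(seq_len(reps), 2),
               ct = c(rep(wt_ct[i], reps), rep(mut_ct[i], reps)))
  }))
  ref <- data.frame(gene = "16S",
                    strain = rep(c("wild-type", "mutant"), each = reps),
                    replicate = rep(seq_len(reps), 2), ct = ref_ct)
  qpcr_table(rbind(rows, ref))
}

test_that("delta-delta-Ct follows the closed form", {
  fit <- suppressWarnings(delta_delta_ct(ct_table("gA", 20, 19)))
  expect_equal(coef(fit)$ratio, 2)
  expect_equal(coef(fit)$reciprocal, 0.5)

  flat <- suppressWarnings(delta_delta_ct(ct_table("gA", 20, 20)))
  expect_equal(coef(flat)$ratio, 1)

  ## efficiency enters as the log base
  e15 <- suppressWarnings(delta_delta_ct(ct_table("gA", 20, 19),
                                         efficiency = 1.5))
  expect_equal(coef(e15)$ratio, 1.5)
  expect_warning(delta_delta_ct(ct_table("gA", 20, 19)), "single-replicate")
})

test_that("reference-gene normalization removes per-sample Ct shifts", {
  tab <- ct_table(c("gA", "gB"), c(20, 22), c(19, 24), reps = 3)
  base <- coef(delta_delta_ct(tab))
  shifted <- tab
  shifted$records$ct[shifted$records$strain == "mutant"] <-
    shifted$records$ct[shifted$records$strain == "mutant"] + 2.5
  expect_equal(coef(delta_delta_ct(shifted))$ratio, base$ratio)
})

test_that("noise-free simulated Ct tables return the planted folds exactly", {
  cfg <- qpcr_sim_config(
    genes = data.frame(gene = c("paaE", "yagM", "flat"),
                       fold = c(4.69, 0.0972, 1)),
    replicates = 3, ct_noise_sd = 0, seed = 99)
  tab <- simulate_qpcr(cfg)
  fit <- coef(delta_delta_ct(tab))
  expect_equal(fit$ratio[fit$gene == "paaE"], 4.69)
  expect_equal(fit$ratio[fit$gene == "yagM"], 0.0972)
  expect_equal(fit$ratio[fit$gene == "flat"], 1)
  expect_equal(fit$sd, rep(0, 3))

  ## planted fold 2 at efficiency 2 shifts the mutant by exactly one cycle
  cfg2 <- qpcr_sim_config(data.frame(gene = "g", fold = 2),
                          replicates = 2, ct_noise_sd = 0)
  rec <- simulate_qpcr(cfg2)$records
  g <- rec[rec$gene == "g", ]
  expect_equal(mean(g$ct[g$strain == "wild-type"]) -
                 mean(g$ct[g$strain == "mutant"]), 1)
  ## fold 4.69 corresponds to a ddCt of -log2(4.69)
  rec3 <- simulate_qpcr(qpcr_sim_config(
    data.frame(gene = "p", fold = 4.69), replicates = 2,
    ct_noise_sd = 0))$records
  p <- rec3[rec3$gene == "p", ]
  expect_equal(mean(p$ct[p$strain == "mutant"]) -
                 mean(p$ct[p$strain == "wild-type"]),
               -log2(4.69))
})

test_that("fold classification partitions the input at strict thresholds", {
  t2 <- occ_example_table("qpcr_increased")
  cls <- classify_folds(t2)
  expect_equal(cls$gt4, 7)
  expect_equal(cls$gt2_le4, 6)
  expect_equal(cls$le2, 4)
  expect_equal(cls$gt4 + cls$gt2_le4 + cls$le2, nrow(t2))

  ## boundary convention: "more than" is strict
  cls2 <- classify_folds(c(4, 4.0001, 2, 2.0001, 1))
  expect_equal(cls2, list(gt4 = 1L, gt2_le4 = 2L, le2 = 2L))
  expect_equal(classify_folds(rep(1, 6))$le2, 6)

  set.seed(13)
  r <- exp(rnorm(100))
  cl <- classify_folds(r)
  expect_equal(cl$gt4 + cl$gt2_le4 + cl$le2, 100)
})

test_that("reciprocal tables round as printed", {
  expect_equal(reciprocal_table(10.29)$reciprocal, 0.0972)
  expect_equal(reciprocal_table(1)$reciprocal, 1)
  expect_equal(reciprocal_table(0.0972)$reciprocal, 10.2881)
  expect_error(reciprocal_table(-1), "> 0")
})

test_that("Ct tables validate their contract", {
  expect_error(qpcr_table(data.frame(gene = "g", strain = "wild-type",
                                     replicate = 1, ct = 20)),
               "reference gene")
  expect_error(qpcr_table(data.frame(gene = c("16S", "16S"),
                                     strain = c("wild-type", "mutant"),
                                     replicate = 1, ct = c(10, -1))),
               "Ct values")
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- ct_table("gA", 20, 19, reps = 2)
  write.table(tab$records, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_equal(coef(delta_delta_ct(read_qpcr(path)))$ratio, 2)
})
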
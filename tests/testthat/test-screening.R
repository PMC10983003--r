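test_that("confusion matrix enumerates the four cells correctly", {
  cm <- confusionMatrix(c(-1, -1, 1), c(-1, 1, -1))
  expect_equal(unclass(cm)[c("TP", "TN", "FP", "FN")],
               list(TP = 1L, TN = 0L, FP = 1L, FN = 1L))
  # perfect predictions of mixed sign
  cm2 <- confusionMatrix(c(-0.2, 0.4, -0.1), c(-0.5, 0.3, -0.2))
  expect_equal(cm2$FP + cm2$FN, 0L)
  # no negatives anywhere: nothing positive to find
  cm3 <- confusionMatrix(c(0.1, 0.2), c(0.3, 0))
  expect_equal(cm3$TP + cm3$FN, 0L)
  expect_error(confusionMatrix(1, c(1, 2)), "length mismatch")
})

test_that("classification metrics reproduce every published benchmark row", {
  for (row in publishedMetricRows()) {
    m <- classificationMetrics(asConfusion(row$cm))
    expect_equal(round(m$f1, 2), row$f1, label = paste(row$name, "F1"))
    expect_equal(round(m$roc_auc, 2), row$roc, label = paste(row$name, "ROC-AUC"))
    expect_equal(round(m$accuracy, 2), row$acc, label = paste(row$name, "accuracy"))
    expect_equal(round(m$recall, 2), row$rec, label = paste(row$name, "recall"))
    expect_equal(round(m$specificity, 2), row$spec,
                 label = paste(row$name, "specificity"))
  }
})

test_that("undefined ratios are zero with a flag, and empty matrices error", {
  m <- classificationMetrics(asConfusion(c(0, 10, 0, 0)))
  expect_equal(m$recall, 0)
  expect_equal(m$f1, 0)
  expect_true(all(c("recall", "f1") %in% attr(m, "undefined")))
  expect_error(classificationMetrics(asConfusion(c(0, 0, 0, 0))), "empty")
})

test_that("regression metrics have their closed-form values", {
  ref <- c(-0.3, -0.1, 0.2, 0.5, 0.9)
  expect_equal(regressionMetrics(ref, ref),
               list(r2 = 1, spearman = 1, rmse = 0))
  m <- regressionMetrics(ref + 0.1, ref)
  expect_equal(m$rmse, 0.1, tolerance = 1e-12)
  expect_equal(m$spearman, 1)
  expect_lt(m$r2, 1)
  expect_equal(regressionMetrics(c(3, 2, 1), c(1, 2, 3))$spearman, -1)
  expect_warning(regressionMetrics(c(1, 2), c(5, 5)), "constant")
})

test_that("screen produces one record per manifest row and survives failures", {
  dir <- tempfile(); dir.create(dir)
  writeXYZ(pentaleneD2h(), file.path(dir, "pentalene.xyz"))
  writeXYZ(ringPolygon(4L, 1.4), file.path(dir, "cbd.xyz"))
  writeXYZ(polyeneChain(4L), file.path(dir, "butadiene.xyz"))
  # a structure the parameter table cannot handle (phosphorus center)
  writeLines(c("3", "phosphine-like", "C 0 0 0", "C 1.4 0 0", "P 2.8 0 0"),
             file.path(dir, "phos.xyz"))
  manifest <- data.frame(
    id = c("pentalene", "cbd", "butadiene", "phos"),
    structure_path = c("pentalene.xyz", "cbd.xyz", "butadiene.xyz", "phos.xyz"),
    ref_gap_eV = c(-0.2, -0.1, 3.0, 0.5)
  )
  man_path <- file.path(dir, "manifest.csv")
  write.csv(manifest, man_path, row.names = FALSE)
  out_path <- file.path(dir, "results.csv")
  expect_message(res <- screen(man_path, out = out_path), "3 molecules|4 molecules")
  expect_equal(nrow(res), 4L)
  expect_equal(attr(res, "n_failed"), 1L)
  expect_match(res$status[res$id == "phos"], "^failed:")
  expect_true(all(res$status[res$id != "phos"] == "ok"))
  expect_true(res$inverted[res$id == "pentalene"])
  expect_false(res$inverted[res$id == "butadiene"])
  expect_true(file.exists(out_path))
  back <- read.csv(out_path)
  expect_equal(nrow(back), 4L)

  # metrics on the scored subset
  rep <- metricsReport(res)
  expect_equal(rep$n, 3L)
  expect_s3_class(rep$confusion, "ppp_confusion")

  # empty manifest: empty output, no error
  empty <- manifest[0, ]
  res0 <- suppressMessages(screen(empty, base_dir = dir))
  expect_equal(nrow(res0), 0L)
})

test_that("config round-trips through YAML including correction coefficients", {
  cfg <- pppConfig(lc = list(slope = 0.61, intercept = -0.08),
                   scf = list(tol = 1e-10))
  path <- tempfile(fileext = ".yaml")
  writeConfig(cfg, path)
  cfg2 <- readConfig(path)
  expect_equal(cfg2$lc$slope, 0.61)
  expect_equal(cfg2$lc$intercept, -0.08)
  expect_equal(cfg2$scf$tol, 1e-10)
  # untouched keys keep defaults
  expect_equal(cfg2$classify$level, "gap_cis_dsp")
})
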
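test_that("descriptor tables round-trip through write/read identically", {
  set.seed(42)
  X <- matrix(rnorm(12), 3, 4,
              dimnames = list(c("75a", "81d", "c3"), c("X5A", "TIE", "Gu", "Ku")))
  ds <- qsar_dataset(X, activities = c(3.82, 2.80, 4.70))
  path <- tempfile(fileext = ".csv")
  write_descriptor_table(ds, path)
  ds2 <- read_descriptor_table(path)
  expect_equal(ds2$X, ds$X, tolerance = 0)
  expect_identical(ds2$compound_ids, ds$compound_ids)
  expect_identical(ds2$descriptor_names, ds$descriptor_names)
  expect_equal(ds2$activities, ds$activities, tolerance = 0)
})

test_that("malformed descriptor tables are rejected with located errors", {
  path <- write_raw_csv(c("compound_id,pIC50,X5A,Gu",
                          "c1,4.2,0.51,1.0",
                          "c2,4.0,,1.1",
                          "c3,3.9,0.48,0.9"))
  expect_error(read_descriptor_table(path), "c2.*X5A")

  path <- write_raw_csv(c("compound_id,pIC50,X5A",
                          "81d,4.2,0.51",
                          "81d,4.0,0.52"))
  expect_error(read_descriptor_table(path), "duplicate compound ID.*81d")

  path <- write_raw_csv(c("compound_id,pIC50,X5A",
                          "c1,4.2,abc"))
  expect_error(read_descriptor_table(path), "c1.*X5A")

  expect_error(qsar_dataset(matrix(c(1, NA), 2, 1), c(1, 2)), "non-finite")
  expect_error(qsar_dataset(matrix(1:4, 2, 2,
                                   dimnames = list(NULL, c("a", "a"))),
                            c(1, 2)),
               "duplicate descriptor")
})

test_that("tab-delimited tables are sniffed and parsed", {
  path <- write_raw_csv(c("compound_id\tpIC50\tX5A\tGu",
                          "c1\t4.2\t0.51\t1.0",
                          "c2\t4.0\t0.52\t1.1",
                          "c3\t3.9\t0.48\t0.9"))
  ds <- read_descriptor_table(path)
  expect_identical(dim(ds), c(3L, 2L))
  expect_identical(ds$descriptor_names, c("X5A", "Gu"))
})

test_that("IC50/pIC50 conversion follows the millimolar convention", {
  expect_equal(round(ic50_to_pic50(0.153), 2), 3.82)
  expect_equal(round(ic50_to_pic50(0.020), 2), 4.70)
  expect_equal(ic50_to_pic50(1000), 0)
  expect_equal(ic50_to_pic50(1, unit = "mM"), 0)
  expect_equal(ic50_to_pic50(0.153, unit = "uM"),
               ic50_to_pic50(153, unit = "nM"))
  expect_error(ic50_to_pic50(0), "positive")
  expect_error(ic50_to_pic50(-1), "positive")
  # inverse composes to identity across twelve decades
  grid <- 10^seq(-6, 6, by = 0.5)
  back <- pic50_to_ic50(ic50_to_pic50(grid))
  expect_true(all(abs(back - grid) / grid < 1e-12))
})

test_that("packaged activity and IC50 tables match the printed values", {
  tab5 <- hsp90_activity_table()
  expect_identical(nrow(tab5), 50L)
  expect_equal(tab5$pic50_exp[tab5$compound_id == "69"], 4.70)
  expect_equal(tab5$pic50_mlr[tab5$compound_id == "15"], 3.64)
  expect_equal(tab5$pic50_gapls[tab5$compound_id == "81d"], 4.42)

  tab7 <- hsp90_ic50_table()
  expect_identical(nrow(tab7), 25L)
  expect_true(all(tab7$ic50_um > 0))
  expect_true(all(tab7$compound_id %in% tab5$compound_id))
  # converted IC50 reproduces the experimental pIC50 for every shared
  # compound within the combined rounding tolerance of both tables
  conv <- ic50_to_pic50(tab7$ic50_um)
  exp_pic50 <- tab5$pic50_exp[match(tab7$compound_id, tab5$compound_id)]
  expect_true(all(abs(conv - exp_pic50) <= 0.015))
})

test_that("every descriptor of the published equations resolves in the catalog", {
  cat_names <- descriptor_catalog()$name
  for (eq in published_models()) {
    expect_true(all(names(eq$coefficients) %in% cat_names),
                label = paste("catalog covers", eq$name))
  }
  expect_identical(anyDuplicated(cat_names), 0L)
})
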
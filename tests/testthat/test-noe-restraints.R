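# ISPA calibration, category binning, bookkeeping and restraint writing.

mk_peaks <- function(vols, res_i = NULL, res_j = NULL) {
  n <- length(vols)
  noe_peaks(res_i = if (is.null(res_i)) rep(1, n) else res_i,
            atom_i = c("H5", rep("H1'", n - 1)),
            res_j = if (is.null(res_j)) rep(1, n) else res_j,
            atom_j = c("H6", rep("H6", n - 1)),
            volume = vols)
}

test_that("ISPA calibration follows the inverse sixth power", {
  pk <- calibrate_distances(mk_peaks(c(1, 1, 1 / 64, 1 / 8)))
  expect_equal(pk$r[1], 2.45)            # reference distance
  expect_equal(pk$r[2], 2.45)            # equal volume -> equal distance
  expect_equal(pk$r[3], 2 * 2.45)        # V/64 -> 2 r_ref
  expect_equal(pk$r[4], 2.45 * 8^(1 / 6), tolerance = 1e-12)
  expect_equal(round(pk$r[4], 2), 3.46)
  expect_error(calibrate_distances(mk_peaks(1), list(res = 3, atom_i = "H5",
                                                     atom_j = "H6",
                                                     distance = 2.45)),
               "not found")
})

test_that("calibration is scale-invariant and monotone", {
  set.seed(31)
  vols <- exp(rnorm(100))
  p1 <- calibrate_distances(mk_peaks(c(1, vols)))
  p2 <- calibrate_distances(mk_peaks(c(1, vols) * 137.5))
  expect_equal(p1$r, p2$r, tolerance = 1e-12)
  ord <- order(p1$volume)
  expect_true(all(diff(p1$r[ord]) <= 1e-12))
})

test_that("categories carry the canonical bounds and boundary rules", {
  # distances at 2.5, 3.5, exactly 4.5 (half-open boundary -> weak), 6.2
  pk <- mk_peaks(rep(1, 5))[-1, ]
  class(pk) <- c("noe_peaks", "data.frame")
  pk$r <- c(2.5, 3.5, 4.5, 6.2)
  restr <- assign_categories(pk)
  expect_equal(restr$category, c("strong", "medium", "weak", "very weak"))
  expect_equal(restr$lower, c(1.8, 1.8, 3.0, 4.0))
  expect_equal(restr$upper, c(3.0, 4.5, 6.0, 7.0))
  bounds <- noe_category_bounds()
  expect_equal(bounds$lower, c(1.8, 1.8, 3.0, 4.0))
  expect_equal(bounds$upper, c(3.0, 4.5, 6.0, 7.0))
})

test_that("category assignment partitions the distance axis", {
  set.seed(8)
  tab <- generate_noe_peak_table(1000, 28, seed = 8)
  restr <- assign_categories(calibrate_distances(tab$peaks))
  expect_equal(nrow(restr), 1000)
  counts <- table(restr$category)
  expect_equal(sum(counts), 1000)
  expect_true(all(restr$lower < restr$upper))
  # each restraint's distance is consistent with exactly one category
  recat <- cut(restr$r, c(0, 3, 4.5, 6, Inf), right = FALSE,
               labels = c("strong", "medium", "weak", "very weak"))
  expect_equal(as.character(recat), restr$category)
})

test_that("range classes and table bookkeeping follow |i - j|", {
  pk <- calibrate_distances(
    mk_peaks(c(1, 0.5, 0.4, 0.3), res_i = c(1, 2, 2, 2),
             res_j = c(1, 2, 3, 7)))
  restr <- assign_categories(pk)
  expect_equal(restr$range_class,
               c("intra", "intra", "sequential", "long-range"))
  cnt <- classify_and_count(restr, n_residues = 4,
                            mismatch_residues = c(7))
  expect_equal(cnt$total, 4)
  expect_equal(cnt$intra, 2)
  expect_equal(cnt$sequential, 1)
  expect_equal(cnt$long_range, 1)
  expect_equal(cnt$mismatch, 1)
  expect_equal(cnt$per_residue, 1)
  empty <- classify_and_count(restr[0, ], n_residues = 4)
  expect_equal(empty$total, 0)
  expect_equal(empty$per_residue, 0)
})

test_that("a 958-peak table over 28 residues gives 34.21 per residue", {
  tab <- generate_noe_peak_table(958, 28, seed = 42)
  restr <- assign_categories(calibrate_distances(tab$peaks))
  cnt <- classify_and_count(restr, n_residues = 28)
  expect_equal(cnt$total, 958)
  expect_equal(cnt$per_residue, 34.21)
})

test_that("the XPLOR writer emits the exact assign template", {
  pk <- calibrate_distances(
    mk_peaks(c(1, (2.45 / 2.5)^6), res_i = c(1, 4), res_j = c(1, 5)))
  restr <- assign_categories(pk)[-1, ]
  restr$atom_i <- "H1'"; restr$atom_j <- "H6"
  class(restr) <- c("noe_restraints", "data.frame")
  tmp <- withr::local_tempfile(fileext = ".tbl")
  write_restraints(restr, tmp, dialect = "xplor")
  expect_identical(
    readLines(tmp),
    "assign (resid 4 and name H1') (resid 5 and name H6) 2.4 0.6 0.6")
  expect_error(write_restraints(restr[0, ], tmp, "xplor"), "no restraints")
  expect_error(write_restraints(restr, tmp, "nmrstar"), "arg")
})

test_that("TSV restraint round trip preserves all fields", {
  tab <- generate_noe_peak_table(50, 14, seed = 3)
  restr <- assign_categories(calibrate_distances(tab$peaks))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_restraints(restr, tmp, dialect = "tsv")
  back <- read_restraints_tsv(tmp)
  expect_equal(as.data.frame(back), as.data.frame(restr), tolerance = 1e-10)
})
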
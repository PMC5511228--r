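write_csv_fixture <- function(lines) {
  tf <- tempfile(fileext = ".csv")
  writeLines(lines, tf)
  tf
}

test_that("occurrence loading collapses duplicates and validates structure", {
  tf <- write_csv_fixture(c("species,island,period",
                            "sp1,i1,P1", "sp1,i1,P1", "sp2,i1,P2"))
  expect_message(occ <- read_occurrences(tf), "3 occurrence records \\(2 after")
  expect_equal(nrow(occ), 2)
  expect_s3_class(occ, "occurrence_table")

  # tab-delimited input and positional column fallback
  tf2 <- tempfile(fileext = ".tsv")
  writeLines(c("sp\tisl\tper", "a\ti1\tP1"), tf2)
  expect_equal(nrow(read_occurrences(tf2, sep = "\t", quiet = TRUE)), 1)

  # missing columns is a format error; empty file an empty-input error
  tf3 <- write_csv_fixture(c("species,island", "a,i1"))
  expect_error(read_occurrences(tf3), "must provide columns")
  tf4 <- tempfile(); file.create(tf4)
  expect_error(read_occurrences(tf4), "empty input")
})

test_that("island and trait tables enforce their invariants", {
  isl <- write_csv_fixture(c("island,area_km2", "i1,1.5", "i2,224"))
  expect_equal(read_islands(isl)$area_km2, c(1.5, 224))
  bad <- write_csv_fixture(c("island,area_km2", "i1,1.5", "i1,2"))
  expect_error(read_islands(bad), "duplicate island")
  neg <- write_csv_fixture(c("island,area_km2", "i1,-3"))
  expect_error(read_islands(neg), "positive")

  tr <- write_csv_fixture(c("species,origin,functional_type",
                            "a,native,AH", "b,alien,W"))
  expect_equal(read_traits(tr)$origin, c("native", "alien"))
  badtr <- write_csv_fixture(c("species,origin,functional_type", "a,exotic,AH"))
  expect_error(read_traits(badtr), "unknown origin")
})

test_that("referential integrity is strict by default, flagged when lenient", {
  occ <- make_occ(list("a", "i1", "P1"), list("b", "iX", "P1"))
  islands <- data.frame(island = "i1", area_km2 = 1)
  traits <- data.frame(species = c("a", "b"), origin = "native",
                       functional_type = "AH")
  expect_error(validate_dataset(occ, islands, traits), "unknown islands")
  expect_warning(res <- validate_dataset(occ, islands, traits, strict = FALSE),
                 "flagged")
  expect_equal(attr(res, "unknown_islands"), "iX")
})

test_that("occurrence tables round-trip through delimited text", {
  occ <- make_occ(list("a", "i1", "P1"), list("b", "i2", "P2"),
                  list("a", "i2", "P1"))
  tf <- tempfile(fileext = ".csv")
  write_occurrences(occ, tf)
  back <- read_occurrences(tf, quiet = TRUE)
  expect_equal(as.data.frame(back)[order(back$species, back$island), ],
               as.data.frame(occ)[order(occ$species, occ$island), ],
               ignore_attr = TRUE)
})

test_that("incidence matrices have period-specific rows, island-table columns", {
  occ <- make_occ(list("a", "i1", "P1"), list("a", "i2", "P1"),
                  list("b", "i1", "P1"), list("c", "i1", "P2"))
  islands <- data.frame(island = c("i1", "i2", "i3"), area_km2 = c(1, 10, 100))
  m <- build_incidence(occ, islands, "P1")
  expect_equal(dim(m), c(2L, 3L))               # species c absent from P1
  expect_equal(colnames(m), islands$island)      # island-table order
  expect_equal(unname(colSums(m)), c(2, 1, 0))   # all-zero column retained
  expect_equal(matrix_fill(m[, 1:2]), 3 / 4)
  expect_equal(richness_by_island(m)$richness, c(2L, 1L, 0L))

  # idempotent with respect to duplicate records
  m2 <- build_incidence(rbind(occ, occ), islands, "P1")
  expect_equal(unclass(m), unclass(m2), ignore_attr = TRUE)

  expect_error(build_incidence(occ, islands, "P9"), "period not present")
})

test_that("group filters partition occurrences without losing any", {
  set.seed(11)
  arch <- generate_archipelago(small_config(seed = 11))
  occ <- arch$occurrences
  p1 <- sort(unique(occ$period))[1]
  total <- build_incidence(occ, arch$islands, p1)
  by_origin <- lapply(c("native", "alien"), function(o)
    build_incidence(occ, arch$islands, p1, arch$traits, origin = o))
  expect_equal(sum(total), sum(vapply(by_origin, sum, numeric(1))))
  by_ft <- lapply(c("AH", "PH", "W"), function(f)
    build_incidence(occ, arch$islands, p1, arch$traits, functional_type = f))
  expect_equal(sum(total), sum(vapply(by_ft, sum, numeric(1))))

  expect_error(
    build_incidence(make_occ(list("a", "i1", "P1")),
                    data.frame(island = "i1", area_km2 = 1), "P1",
                    data.frame(species = "a", origin = "native",
                               functional_type = "AH"), origin = "alien"),
    "no occurrence records")
})
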
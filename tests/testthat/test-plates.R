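test_that("grid files parse into one reading per plate x timepoint", {
  path <- withr::local_tempfile(fileext = ".csv")
  block <- matrix(0.5, 8, 12)
  write_grid_file(path, list(c("PL1", "S1", 24), c("PL1", "S1", 72)),
                  list(block, block + 0.3))
  readings <- read_ecoplate(path, layout = "grid")
  expect_length(readings, 2)
  expect_equal(vapply(readings, `[[`, 0, "time_h"), c(24, 72))
  expect_length(readings[[1]]$od, 96)
  expect_equal(unname(readings[[2]]$od[["A1"]]), 0.8)
})

test_that("malformed plate files raise located parse errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  block <- matrix(0.5, 8, 12)
  write_grid_file(path, list(c("PL1", "S1", 24)), list(block))
  txt <- readLines(path)
  writeLines(txt[-length(txt)], path)              # drop row H
  expect_error(read_ecoplate(path, layout = "grid"), "row H missing")

  bad <- sub("^H,0.5", "H,oops", txt)
  writeLines(bad, path)
  expect_error(read_ecoplate(path, layout = "grid"), "non-numeric OD")

  write_grid_file(path, list(c("PL1", "S1", 24), c("PL1", "S1", 24)),
                  list(block, block))
  expect_error(read_ecoplate(path, layout = "grid"), "duplicated timepoint")
})

test_that("long files accept wells or substrate codes and demand 96 wells", {
  wells <- as.vector(vapply(1:12, function(j) paste0(LETTERS[1:8], j),
                            character(8)))
  df <- data.frame(sample_id = "S1", well = wells, time_h = 96,
                   od = seq(0.1, 1.05, length.out = 96))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  readings <- read_ecoplate(path, layout = "long")
  expect_length(readings, 1)
  expect_length(readings[[1]]$od, 96)

  write.csv(df[df$well != "H12", ], path, row.names = FALSE)
  expect_error(read_ecoplate(path, layout = "long"),
               "96 wells expected, 95 found")

  df2 <- data.frame(sample_id = "S1", substrate_code = catalog$code,
                    time_h = 96, od = runif(32, 0.2, 2))
  write.csv(df2, path, row.names = FALSE)
  readings <- read_ecoplate(path, layout = "long")
  expect_length(readings[[1]]$od, 32)
})

test_that("blank correction subtracts the block water well and clips at 0", {
  vals <- rep(0.15, 32)                   # water baseline everywhere
  vals[water_index] <- 0.15
  i_ch5 <- which(catalog$code == "CH5")
  vals[i_ch5] <- 1.50
  i_p3 <- which(catalog$code == "P3")
  vals[i_p3] <- 0.10                      # below water: clips to 0
  reading <- list(plate_id = "PL1", sample_id = "S1", time_h = 96,
                  od = grid_od(vals))
  prof <- blank_correct(reading, catalog)
  expect_s3_class(prof, "sample_profile")
  expect_length(prof$x, 31)
  expect_equal(unname(prof$x[["CH5"]]), 1.35)
  expect_equal(unname(prof$x[["P3"]]), 0)
  expect_true(all(prof$x >= 0))
  expect_equal(prof$total, sum(prof$x))
})

test_that("replicate blocks are averaged after per-block correction", {
  od <- grid_od(rep(0.2, 32))
  i_ch5 <- which(catalog$code == "CH5")
  for (b in 1:3) {                        # blocks read 1.0 / 1.2 / 1.4
    col <- (b - 1) * 4 + (i_ch5 - 1) %/% 8 + 1
    row <- (i_ch5 - 1) %% 8 + 1
    od[paste0(LETTERS[row], col)] <- c(1.0, 1.2, 1.4)[b]
  }
  prof <- blank_correct(list(sample_id = "S1", time_h = 96, od = od), catalog)
  expect_equal(unname(prof$x[["CH5"]]), 1.0)
  expect_equal(unname(prof$x[["CH2"]]), 0)  # 0.2 - 0.2 water
})

test_that("blank correction is idempotent once water reads zero", {
  set.seed(7)
  vals <- runif(32, 0, 2)
  vals[water_index] <- 0
  prof1 <- blank_correct(list(sample_id = "S", time_h = 1,
                              od = grid_od(vals)), catalog)
  again <- c(prof1$x, W = 0)
  prof2 <- blank_correct(list(sample_id = "S", time_h = 1, od = again),
                         catalog)
  expect_equal(prof2$x, prof1$x)
})

test_that("plateau selection honours policy, ties and warnings", {
  mk <- function(t, level) list(plate_id = "PL", sample_id = "S", time_h = t,
                                od = grid_od(rep(level, 32)) +
                                  grid_od(c(0, rep(0.5 * level, 31))))
  series <- list(mk(24, 0.2), mk(72, 1.1), mk(120, 1.0))
  expect_equal(select_plateau(series, "last")$time_h, 120)
  expect_equal(select_plateau(series, "max_awcd", catalog)$time_h, 72)
  # 96 h is equidistant from 72 and 120: the tie breaks toward the later one
  expect_equal(suppressWarnings(select_plateau(series, "fixed:96"))$time_h, 120)
  expect_warning(sel <- select_plateau(series[1], "fixed:96"), "> 12 h")
  expect_equal(sel$time_h, 24)
  expect_error(select_plateau(list(), "last"), "empty")
})

test_that("long-format profiles round-trip losslessly", {
  set.seed(11)
  m <- rbind(S1 = rand_profile(), S2 = rand_profile())
  path <- withr::local_tempfile(fileext = ".csv")
  write_profiles(m, path)
  back <- read_profiles(path)
  expect_equal(back[rownames(m), colnames(m)], m, tolerance = 1e-12)
})

test_that("design validation enforces uniqueness and control replicates", {
  d <- data.frame(sample_id = c("a", "b", "c"),
                  treatment = c("V1", "V1", "V2"), replicate = c(1, 2, 1))
  expect_silent(validate_design(d, control = "V1"))
  expect_error(validate_design(d, control = "V9"), "'V9' not found")
  expect_error(validate_design(rbind(d, d[1, ])), "duplicated sample_id")
  expect_error(validate_design(d[c(1, 3), ], control = "V1"),
               "at least 2 replicates")
})
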
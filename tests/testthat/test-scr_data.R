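test_that("trap reader validates and round-trips", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(trap_id = sprintf("T%02d", 1:29),
                   x = runif(29, 0, 10), y = runif(29, 0, 10))
  write.csv(df, f, row.names = FALSE, quote = FALSE)
  tr <- read_traps(f)
  expect_s3_class(tr, "trap_array")
  expect_length(tr$trap_id, 29)
  expect_equal(unname(tr$coords[, "x"]), df$x)

  # round-trip, including an operation mask
  tr2 <- trap_array(df$trap_id, df$x, df$y,
                    operation = matrix(rbinom(29 * 4, 1, 0.8), 29, 4))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_traps(tr2, f2)
  tr3 <- read_traps(f2)
  expect_equal(tr3$coords, tr2$coords)
  expect_equal(tr3$operation, tr2$operation)

  writeLines("trap_id,x,y", f)
  expect_error(read_traps(f), "no traps")
  writeLines(c("trap_id,x,y", "T1,0,0", "T1,1,1"), f)
  expect_error(read_traps(f), "duplicate trap id")
  writeLines(c("trap_id,x,y", "T1,0,0", "T2,oops,1"), f)
  expect_error(read_traps(f), "non-numeric x coordinate in row 2")
})

test_that("capture reader builds a binary history and validates", {
  traps <- toy_traps(4)
  cal <- occasion_calendar(91, "daily")
  rec <- data.frame(
    individual = c("a", "a", "a", "b", "b"),
    trap_id = c("T1", "T1", "T2", "T3", "T3"),
    day = c(3, 3, 10, 91, 91),
    sex = c("F", "F", "U", "M", "M"))
  h <- captures_from_records(rec, traps, cal)
  expect_equal(dim(h$y), c(2L, 4L, 91L))
  # duplicate same-cell records collapse to a single 1
  expect_equal(sum(h$y), 3)
  expect_equal(h$y["a", "T1", 3], 1L)
  expect_equal(h$sex, c(a = "F", b = "M"))

  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(rec, f, row.names = FALSE, quote = FALSE)
  expect_equal(read_captures(f, traps, cal)$y, h$y)

  rec_bad <- rec; rec_bad$trap_id[1] <- "T9"
  expect_error(captures_from_records(rec_bad, traps, cal),
               "unknown trap id")
  rec_bad <- rec; rec_bad$day[1] <- 92
  expect_error(captures_from_records(rec_bad, traps, cal),
               "outside the calendar")
  rec_bad <- rec; rec_bad$sex[3] <- "M"   # individual "a" both F and M
  expect_error(captures_from_records(rec_bad, traps, cal),
               "conflicting sex labels")
})

test_that("capture history round-trips through the long format", {
  traps <- toy_traps(6)
  for (seed in 1:3) {
    h <- random_history(5, traps, 12, seed)
    dimnames(h$y)[[1]] <- paste0("ind", 1:5)
    f <- withr::local_tempfile(fileext = ".csv")
    write_captures(h, f)
    h2 <- read_captures(f, traps, h$calendar)
    ids <- dimnames(h$y)[[1]]
    expect_equal(unname(h2$y[ids, , ]), unname(h$y))
    expect_equal(unname(h2$sex[ids]), h$sex)
  }
})

test_that("occasion calendars match the printed occasion counts", {
  expect_equal(nrow(occasion_calendar(91, "daily")$blocks), 91)
  expect_equal(nrow(occasion_calendar(91, "weekly")$blocks), 13)
  expect_equal(occasion_calendar(91, "monthly")$blocks$length,
               c(30L, 30L, 31L))
  expect_equal(occasion_calendar(90, "monthly")$blocks$length,
               c(30L, 30L, 30L))
  expect_equal(occasion_calendar(90, "weekly")$blocks$length,
               c(rep(7L, 12), 6L))
  expect_equal(nrow(occasion_calendar(90, "quarterly")$blocks), 1)
  expect_error(occasion_calendar(10, "custom", lengths = c(3, 3)),
               "cover the full study duration")
})

test_that("occasion aggregation ORs within blocks", {
  traps <- toy_traps(1)
  # 1s on days 2 and 5 of a single 7-day block -> one collapsed 1
  y <- array(0L, c(1, 1, 7)); y[1, 1, c(2, 5)] <- 1L
  h <- capture_history(y, "F", occasion_calendar(7, "daily"), traps)
  wk <- aggregate_occasions(h, "weekly")
  expect_equal(dim(wk$y)[3], 1L)
  expect_equal(sum(wk$y), 1)

  h91 <- random_history(4, toy_traps(4), 91, seed = 42)
  expect_equal(dim(aggregate_occasions(h91, "weekly")$y)[3], 13L)
  # identity scheme leaves the history unchanged
  expect_equal(aggregate_occasions(h91, h91$calendar)$y, h91$y)
})

test_that("aggregation is idempotent, monotone, and keeps individuals", {
  traps <- toy_traps(5)
  for (seed in 1:5) {
    h <- random_history(6, traps, 30, seed)
    counts <- sapply(c("daily", "weekly", "monthly", "quarterly"),
                     function(sc) sum(aggregate_occasions(h, sc)$y))
    expect_true(all(diff(counts) <= 0))   # daily >= ... >= quarterly
    wk <- aggregate_occasions(h, "weekly")
    expect_equal(aggregate_occasions(wk, wk$calendar)$y, wk$y)
    expect_equal(dim(wk$y)[1], dim(h$y)[1])
    expect_equal(wk$sex, h$sex)
  }
  # misaligned scheme: weekly blocks cut across monthly source blocks
  hm <- aggregate_occasions(random_history(3, traps, 30, 9), "monthly")
  expect_error(aggregate_occasions(hm, "weekly"), "align")
})

test_that("operation masks collapse with the history", {
  traps <- toy_traps(2)
  op <- matrix(1L, 2, 14); op[2, 1:7] <- 0L
  traps$operation <- op
  y <- array(0L, c(1, 2, 14)); y[1, 1, 2] <- 1L; y[1, 2, 9] <- 1L
  h <- capture_history(y, "F", occasion_calendar(14, "daily"), traps)
  wk <- aggregate_occasions(h, "weekly")
  expect_equal(wk$traps$operation, matrix(c(1L, 1L, 0L, 1L), 2, 2,
                                          byrow = TRUE))
})

test_that("statespace geometry follows the buffered rectangle", {
  # single trap at origin, buffer b: extent side 2b
  tr1 <- trap_array("T1", 0, 0)
  sp <- build_statespace(tr1, buffer = 3, spacing = 0.5)
  expect_equal(unname(sp$extent), c(-3, 3, -3, 3))
  expect_equal(sp$total_area, 36, tolerance = 1e-12)

  # 8x8 unit grid, buffer 2, spacing 0.5: count pixels by enumeration
  g <- expand.grid(x = 0:7, y = 0:7)
  tr <- trap_array(seq_len(64), g$x, g$y)
  sp <- build_statespace(tr, buffer = 2, spacing = 0.5)
  gx <- seq(-2 + 0.25, 9 - 0.25, by = 0.5)
  expect_equal(nrow(sp$pixel_centers), length(gx)^2)
  expect_equal(sp$total_area, length(gx)^2 * 0.25)
  # all traps inside the extent
  expect_true(all(tr$coords[, "x"] >= sp$extent["xmin"] &
                    tr$coords[, "x"] <= sp$extent["xmax"]))

  # disc mask drops rectangle corners
  spd <- build_statespace(tr1, buffer = 3, spacing = 0.5, mask = "disc")
  expect_lt(nrow(spd$pixel_centers), nrow(sp$pixel_centers))
  d <- sqrt(rowSums(spd$pixel_centers^2))
  expect_true(all(d <= 3 + 1e-6))

  expect_error(build_statespace(tr1, buffer = 1, spacing = 5),
               "degenerate statespace")
})

test_that("statespace export writes one row per pixel", {
  sp <- build_statespace(toy_traps(4), buffer = 1, spacing = 0.5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_statespace(sp, f)
  df <- read.csv(f)
  expect_equal(nrow(df), nrow(sp$pixel_centers))
  expect_equal(df$area, rep(sp$pixel_area, nrow(df)))
})
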
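make_grid <- function(nr = 3, nc = 3, wf = 1) {
  rows <- rep(seq_len(nr), each = nc)
  cols <- rep(seq_len(nc), times = nr)
  data.frame(pixel_id = sprintf("p%02d", seq_len(nr * nc)),
             row = rows, col = cols,
             x_center = (cols - 0.5) * 240,
             y_center = (nr - rows + 0.5) * 240,
             woodland_fraction = wf)
}

test_that("box at a pixel centre inherits that pixel's date", {
  grid <- make_grid()
  gu <- data.frame(pixel_id = grid$pixel_id, year = 2001,
                   greenup_day = 100 + seq_len(9))
  box <- list(x = grid$x_center[5], y = grid$y_center[5])
  r <- nestbox_greenup(box, gu, grid)
  expect_equal(r$greenup_day, gu$greenup_day[5])
  expect_identical(r$status, "ok")
})

test_that("equal neighbour dates give that date regardless of position", {
  grid <- make_grid()
  gu <- data.frame(pixel_id = grid$pixel_id, year = 2001,
                   greenup_day = 105)
  for (i in 1:5) {
    box <- list(x = runif(1, 120, 600), y = runif(1, 120, 600))
    expect_equal(nestbox_greenup(box, gu, grid)$greenup_day, 105)
  }
})

test_that("zero woodland fraction removes a pixel's weight", {
  # 1-row grid: A at woodland 1 (day 100), B at woodland 0 (day 200)
  grid <- data.frame(pixel_id = c("A", "B"), row = 1, col = 1:2,
                     x_center = c(120, 360), y_center = 120,
                     woodland_fraction = c(1, 0))
  gu <- data.frame(pixel_id = c("A", "B"), year = 2001,
                   greenup_day = c(100, 200))
  box <- list(x = 240, y = 120) # midway
  expect_equal(nestbox_greenup(box, gu, grid)$greenup_day, 100)
})

test_that("result is a convex combination of contributing dates", {
  set.seed(11)
  grid <- make_grid(4, 4, wf = runif(16, 0.2, 1))
  gu <- data.frame(pixel_id = grid$pixel_id, year = 2001,
                   greenup_day = runif(16, 95, 130))
  for (i in 1:20) {
    box <- list(x = runif(1, 0, 960), y = runif(1, 0, 960))
    r <- nestbox_greenup(box, gu, grid)
    expect_true(r$greenup_day >= min(gu$greenup_day) - 1e-9)
    expect_true(r$greenup_day <= max(gu$greenup_day) + 1e-9)
  }
})

test_that("continuity under small moves of the box", {
  grid <- make_grid(3, 3, wf = 0.8)
  gu <- data.frame(pixel_id = grid$pixel_id, year = 2001,
                   greenup_day = 100 + seq_len(9))
  b0 <- nestbox_greenup(list(x = 300, y = 300), gu, grid)
  b1 <- nestbox_greenup(list(x = 300.5, y = 300.3), gu, grid)
  expect_lt(abs(b1$greenup_day - b0$greenup_day), 0.1)
})

test_that("unassignable boxes fall back then drop, with reasons", {
  grid <- make_grid(3, 3, wf = 0)
  grid$woodland_fraction[1] <- 1 # only the NW pixel is woodland
  gu <- data.frame(pixel_id = grid$pixel_id, year = 2001,
                   greenup_day = c(111, rep(NA, 8)))
  near <- nestbox_greenup(list(x = 360, y = 600), grid = grid,
                          greenup_year = gu)
  expect_identical(near$status, "fallback")
  expect_equal(near$greenup_day, 111)
  far <- nestbox_greenup(list(x = 700, y = 100), grid = grid,
                         greenup_year = gu)
  expect_identical(far$status, "NotAssignable")
  expect_true(is.na(far$greenup_day))
})

test_that("vectorized table agrees with the single-box routine", {
  set.seed(21)
  grid <- make_grid(4, 4, wf = runif(16, 0, 1))
  gu <- rbind(
    data.frame(pixel_id = grid$pixel_id, year = 2001,
               greenup_day = runif(16, 95, 130)),
    data.frame(pixel_id = grid$pixel_id, year = 2002,
               greenup_day = c(NA, runif(15, 100, 125))))
  nb <- data.frame(box_id = sprintf("b%02d", 1:15),
                   x = runif(15, 0, 960), y = runif(15, 0, 960))
  tab <- nestbox_greenup_table(nb, gu, grid)
  for (i in seq_len(nrow(nb))) {
    for (yr in c(2001, 2002)) {
      single <- nestbox_greenup(nb[i, ], gu[gu$year == yr, ], grid)
      row <- tab[tab$box_id == nb$box_id[i] & tab$year == yr, ]
      expect_equal(row$greenup_day, single$greenup_day, tolerance = 1e-9)
      expect_identical(row$status, single$status)
    }
  }
})

test_that("oak density counts trees within an inclusive 75 m radius", {
  box <- list(x = 0, y = 0)
  expect_identical(oak_density(box, data.frame(x = numeric(0),
                                               y = numeric(0))), 0L)
  expect_identical(oak_density(box, data.frame(x = 75, y = 0)), 1L)
  trees <- data.frame(x = c(10, 74, 76), y = 0)
  expect_identical(oak_density(box, trees), 2L)
})
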
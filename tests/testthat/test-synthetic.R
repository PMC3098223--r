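test_that("wild-type anchor table hits the printed endpoints", {
  obs <- wildtype_reference_observations()
  expect_equal(nrow(obs), 7L)
  first <- obs[obs$internode == "1-2", ]
  expect_equal(c(first$h, first$g, first$s),
               c(7, 85.5, 7.4) / 99.9, tolerance = 1e-12)
  last <- obs[obs$internode == "8", ]
  expect_equal(last$h, 0.01, tolerance = 1e-12)
  expect_equal(last$s / last$g, 0.64, tolerance = 1e-12)
  # h = 0.01 and s/g = 0.64 with h+g+s = 1 pin internode 8 at (.010,.604,.386)
  expect_equal(round(c(last$h, last$g, last$s), 3), c(0.010, 0.604, 0.386))
  # S/G strictly increasing, H share strictly decreasing with maturity
  expect_true(all(diff(obs$s / obs$g) > 0))
  expect_true(all(diff(obs$h) < 0))
  expect_silent(validate_observations(obs))
})

test_that("synthetic study generation is seeded and respects the design", {
  t1 <- generate_synthetic_study(seed = 7)
  t2 <- generate_synthetic_study(seed = 7)
  expect_identical(t1, t2)
  t3 <- generate_synthetic_study(seed = 8)
  expect_false(identical(t1, t3))
  expect_equal(nrow(t1), 49L)
  expect_setequal(unique(t1$line_id), STUDY_LINES)
  expect_silent(validate_observations(t1))
  # noiseless generation reproduces the wild-type anchors exactly
  quiet <- generate_synthetic_study(study_design(noise_sd = 0,
                                                 lignin_noise_sd = 0), seed = 1)
  wt <- quiet[quiet$line_id == "WT", c("h", "g", "s", "total_lignin")]
  ref <- wildtype_reference_observations()[, c("h", "g", "s", "total_lignin")]
  expect_equal(wt, ref, ignore_attr = TRUE, tolerance = 1e-12)
  # line-specific direction of the composition shifts
  at8 <- function(tab, ln, col) tab[tab$line_id == ln & tab$internode == "8", col]
  expect_gt(at8(quiet, "C3H", "h"), at8(quiet, "WT", "h"))
  expect_gt(at8(quiet, "CCoAOMT", "s") / at8(quiet, "CCoAOMT", "g"),
            at8(quiet, "WT", "s") / at8(quiet, "WT", "g"))
  expect_lt(at8(quiet, "COMT", "s") / at8(quiet, "COMT", "g"),
            at8(quiet, "WT", "s") / at8(quiet, "WT", "g"))
  expect_lt(at8(quiet, "C4H", "s") / at8(quiet, "C4H", "g"),
            at8(quiet, "WT", "s") / at8(quiet, "WT", "g"))
})

test_that("replicate S/G noise is near the study's reported spread", {
  set.seed(1)
  sgs <- replicate(200, {
    tab <- generate_synthetic_study(seed = sample.int(1e6, 1))
    row <- tab[tab$line_id == "WT" & tab$internode == "5", ]
    row$s / row$g
  })
  expect_gt(stats::sd(sgs), 0.01)
  expect_lt(stats::sd(sgs), 0.06)
})

test_that("observation CSV round-trips and rejects malformed rows", {
  tab <- generate_synthetic_study(seed = 3)
  tab$note <- paste0("r", seq_len(nrow(tab)))  # unknown column
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(tab, path)
  back <- read_observations(path)
  expect_equal(back$h, tab$h, tolerance = 1e-12)
  expect_equal(back$alpha, tab$alpha)
  expect_equal(back$note, tab$note)
  expect_equal(nrow(back[back$line_id != "WT", ]), 42L)
  # a row failing the percentage-sum check is named
  raw <- utils::read.csv(path)
  raw$h_pct[5] <- raw$h_pct[5] + 20
  utils::write.csv(raw, path, row.names = FALSE)
  expect_error(read_observations(path), "row\\(s\\): 5")
  # missing column
  raw$h_pct <- NULL
  utils::write.csv(raw, path, row.names = FALSE)
  expect_error(read_observations(path), "missing column")
})
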
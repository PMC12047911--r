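# hand-built layout: one beam, three layers, two spots each on a 10 mm grid
layout3 <- tibble::tibble(
  spot_id = 1:6,
  layer_id = rep(1:3, each = 2),
  beam_id = 1L,
  energy_index = rep(c(5L, 2L, 9L), each = 2),
  x_mm = rep(c(0, 10), 3),
  y_mm = 0
)

test_that("delivery order: beams ascending, energies descending, serpentine spots", {
  x <- rep(1, 6)
  seqd <- delivery_sequence(x, layout3)
  expect_equal(unique(seqd$energy_index), c(9L, 5L, 2L))

  # two-beam case: per-beam sequences concatenate
  layout2b <- dplyr::mutate(layout3, beam_id = rep(c(2L, 1L, 1L), each = 2))
  seq2b <- delivery_sequence(rep(1, 6), layout2b)
  expect_equal(unique(seq2b$beam_id), c(1L, 2L))

  # serpentine: second row returns in reverse x
  lay_serp <- tibble::tibble(
    spot_id = 1:4, layer_id = 1L, beam_id = 1L, energy_index = 1L,
    x_mm = c(0, 10, 0, 10), y_mm = c(0, 0, 5, 5)
  )
  s <- delivery_sequence(rep(1, 4), lay_serp)
  expect_equal(s$x_mm, c(0, 10, 10, 0))

  # zero-intensity spots and deselected layers are excluded
  xz <- c(1, 1, 0, 0, 1, 1)
  expect_false(any(delivery_sequence(xz, layout3)$layer_id == 2L))
  s_sel <- delivery_sequence(rep(1, 6), layout3, s = c(1, 1, 0))
  expect_false(any(s_sel$layer_id == 3L))
  expect_error(delivery_sequence(rep(0, 6), layout3), "no active spots")
})

test_that("energy switching time charges 0.7 s down and 5.5 s up", {
  cfg <- delivery_config()
  seqd <- delivery_sequence(rep(1, 6), layout3) # energies 9 -> 5 -> 2
  expect_equal(elst(seqd, cfg), 2 * 0.7)
  # single layer: no transitions
  one <- delivery_sequence(c(1, 1, 0, 0, 0, 0), layout3)
  expect_equal(elst(one, cfg), 0)
  # forced ascending transition between beams
  lay_up <- tibble::tibble(
    spot_id = 1:2, layer_id = 1:2, beam_id = 1:2,
    energy_index = c(1L, 8L), x_mm = 0, y_mm = 0
  )
  expect_equal(elst(delivery_sequence(c(1, 1), lay_up), cfg), 5.5)
})

test_that("spill time converts charge through the beam current", {
  cfg <- delivery_config(protons_per_intensity_unit = 1)
  expect_equal(sspt(numeric(5), cfg), 0)
  # one full minute of charge at 2.6e11 protons/min
  expect_equal(sspt(rep(2.6e11 / 4, 4), cfg), 60)
  x <- runif(10, 0, 5)
  expect_equal(sspt(2 * x, cfg), 2 * sspt(x, cfg))
})

test_that("spot switching combines travel time and magnet preparation", {
  cfg <- delivery_config(
    scan_speed_x_mm_per_s = 10, scan_speed_y_mm_per_s = 10,
    t_magnet_prep_s = 0.001
  )
  # coincident consecutive spots: preparation time only
  lay_co <- tibble::tibble(
    spot_id = 1:2, layer_id = 1L, beam_id = 1L, energy_index = 1L,
    x_mm = c(0, 0), y_mm = c(0, 0)
  )
  expect_equal(sswt(delivery_sequence(c(1, 1), lay_co), cfg), 0.001)
  # 10 mm at 10 mm/s: 1 s travel + 1 ms prep
  lay_tr <- dplyr::mutate(lay_co, x_mm = c(0, 10))
  expect_equal(sswt(delivery_sequence(c(1, 1), lay_tr), cfg), 1.001)
  # lone spot per layer: nothing to switch
  lay_one <- tibble::tibble(
    spot_id = 1:2, layer_id = 1:2, beam_id = 1L, energy_index = 1:2,
    x_mm = 0, y_mm = 0
  )
  expect_equal(sswt(delivery_sequence(c(1, 1), lay_one), cfg), 0)
})

test_that("total delivery time decomposes exactly into its components", {
  case <- tiny_case()
  plan <- run_impt(case, config = fast_admm())
  tt <- total_delivery_time(plan)
  expect_equal(tt$total_s, tt$elst_s + tt$sspt_s + tt$sswt_s)
  expect_true(all(c(tt$elst_s, tt$sspt_s, tt$sswt_s) >= 0))
  # degenerate single-spot plan: spill time only
  lay1 <- tibble::tibble(
    spot_id = 1L, layer_id = 1L, beam_id = 1L, energy_index = 1L,
    x_mm = 0, y_mm = 0
  )
  p1 <- list(x = 5, s = 1L)
  t1 <- total_delivery_time(p1, spots = lay1)
  expect_equal(t1$total_s, t1$sspt_s)
})

test_that("components depend only on their own plan features", {
  cfg <- delivery_config()
  x <- rep(1, 6)
  seqd <- delivery_sequence(x, layout3)
  # scaling intensities changes SSPT only
  seqd2 <- delivery_sequence(2 * x, layout3)
  expect_equal(elst(seqd2, cfg), elst(seqd, cfg))
  expect_equal(sswt(seqd2, cfg), sswt(seqd, cfg))
  expect_equal(sspt(2 * x, cfg), 2 * sspt(x, cfg))
  # moving a spot laterally changes SSWT only
  lay_m <- layout3
  lay_m$x_mm[2] <- 25
  seqm <- delivery_sequence(x, lay_m)
  expect_equal(elst(seqm, cfg), elst(seqd, cfg))
  expect_gt(sswt(seqm, cfg), sswt(seqd, cfg))
})

test_that("dropping layers from a descending sequence never increases ELST", {
  set.seed(2)
  cfg <- delivery_config()
  for (rep in 1:20) {
    nl <- sample(3:8, 1)
    lay <- tibble::tibble(
      spot_id = seq_len(nl), layer_id = seq_len(nl), beam_id = 1L,
      energy_index = sample(seq_len(20), nl), x_mm = 0, y_mm = 0
    )
    x <- rep(1, nl)
    full <- elst(delivery_sequence(x, lay), cfg)
    s <- rep(1L, nl)
    s[sample(nl, 1)] <- 0L
    reduced <- elst(delivery_sequence(x, lay, s = s), cfg)
    expect_lte(reduced, full + 1e-12)
  }
})
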
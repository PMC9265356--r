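test_that("grid partition tiles the extent with partial boundary units", {
  r <- land_raster(matrix(1L, 200, 200), cell_size = 30)  # 6 x 6 km
  expect_equal(partition_grid(r)$n_units, 36)
  r2 <- land_raster(matrix(1L, 200, 217), cell_size = 30)  # 6 x 6.51 km
  p2 <- partition_grid(r2)
  expect_equal(p2$n_units, 42)
  expect_lt(min(p2$units$coverage), 1)
  # partition property: every data cell in exactly one unit
  expect_equal(sum(p2$units$cells), 200 * 217)
  expect_true(all(p2$unit_id > 0))
})

test_that("patch extraction matches flood-fill and igraph oracles", {
  r <- random_ple_raster(50, cell_size = 100, seed = 1)
  part <- partition_grid(r, unit_size = 5000)  # one unit: whole raster
  for (conn in c(4, 8)) {
    pat <- extract_patches(r, part, connectivity = conn)
    lab_bf <- flood_fill_label(r$values, conn)
    lab_ig <- igraph_label(r$values, conn)
    expect_equal(nrow(pat), max(lab_bf))
    expect_equal(nrow(pat), length(unique(lab_ig[lab_ig > 0])))
    expect_equal(sort(pat$cells), sort(tabulate(lab_bf)))
    per_bf <- brute_perimeter(r$values, lab_bf, r$cell_size)
    expect_equal(sort(pat$perimeter_m), sort(per_bf))
  }
})

test_that("connectivity convention decides diagonal adjacency", {
  m <- matrix(2L, 4, 4)
  m[1, 1] <- 1L; m[2, 2] <- 1L  # two diagonal same-class cells
  r <- land_raster(m, cell_size = 100, classes = ple_classes())
  part <- partition_grid(r, unit_size = 400)
  p8 <- extract_patches(r, part, connectivity = 8)
  p4 <- extract_patches(r, part, connectivity = 4)
  expect_equal(sum(p8$class == 1), 1)
  expect_equal(sum(p4$class == 1), 2)
  # checkerboard under rook connectivity: every cell its own patch
  chk <- land_raster((outer(1:10, 1:10, "+") %% 2L) + 1L,
                     cell_size = 100, classes = ple_classes())
  pc <- extract_patches(chk, partition_grid(chk, 1000), connectivity = 4)
  expect_equal(nrow(pc), 100)
})

test_that("patches are clipped at unit boundaries and satisfy bounds", {
  r <- land_raster(matrix(2L, 20, 20), cell_size = 100,
                   classes = ple_classes())  # 2 x 2 km, one class
  part <- partition_grid(r, unit_size = 1000)
  pat <- extract_patches(r, part)
  expect_equal(nrow(pat), 4)        # one patch per unit despite continuity
  expect_true(all(pat$area_m2 == 1e6))
  expect_true(all(pat$perimeter_m == 4000))  # unit boundary edges count
  expect_true(all(pat$perimeter_m >= 4 * sqrt(pat$area_m2) - 1e-9))
})

test_that("SCI has its closed forms and matches direct summation", {
  A <- 1e6
  # single square patch filling the unit: AWMPFD = 1 exactly
  expect_equal(pleconflict:::sci_from_patches(1e6, 4000, A), 1,
               tolerance = 1e-12)
  # square of side 500 m, weight a/A = 0.25
  expect_equal(pleconflict:::sci_from_patches(500^2, 4 * 500, A), 0.25,
               tolerance = 1e-12)
  r <- random_ple_raster(30, cell_size = 100, seed = 3)
  part <- partition_grid(r, unit_size = 1000)
  pat <- extract_patches(r, part)
  ind <- conflict_indices(pat, part)
  for (u in unique(pat$unit)) {
    pu <- pat[pat$unit == u, ]
    direct <- sum(2 * log(0.25 * pu$perimeter_m) / log(pu$area_m2) *
                    pu$area_m2 / part$nominal_area_m2)
    expect_equal(ind$sci[ind$unit == u], direct)
  }
})

test_that("SVI is the area-weighted vulnerability with the nominal-A rule", {
  A <- 1e6
  part <- partition_grid(land_raster(matrix(2L, 10, 10), cell_size = 100,
                                     classes = ple_classes()), 1000)
  # unit entirely production-ecological -> 3
  pat_pe <- tibble::tibble(unit = 1L, patch = 1L, class = 2L, cells = 100L,
                           area_m2 = 1e6, perimeter_m = 4000)
  expect_equal(conflict_indices(pat_pe, part)$svi, 3)
  # half living-production, half ecological -> (4 + 1)/2
  pat_mix <- tibble::tibble(unit = 1L, patch = 1:2, class = c(1L, 4L),
                            cells = 50L, area_m2 = 5e5,
                            perimeter_m = c(3000, 3000))
  expect_equal(conflict_indices(pat_mix, part)$svi, 2.5)
  # partial boundary unit, 40% covered, all living-production -> 4 * 0.4
  pat_part <- tibble::tibble(unit = 1L, patch = 1L, class = 1L, cells = 40L,
                             area_m2 = 4e5, perimeter_m = 4000)
  expect_equal(conflict_indices(pat_part, part)$svi, 1.6)
  # SVI invariant under patch splitting (depends only on class areas)
  pat_split <- tibble::tibble(unit = 1L, patch = 1:4, class = c(1L, 1L, 4L, 4L),
                              cells = 25L, area_m2 = 2.5e5,
                              perimeter_m = 2000)
  expect_equal(conflict_indices(pat_split, part)$svi, 2.5)
  # unknown class code errors
  pat_bad <- tibble::tibble(unit = 1L, patch = 1L, class = 9L, cells = 1L,
                            area_m2 = 1e4, perimeter_m = 400)
  expect_error(conflict_indices(pat_bad, part), "weight")
})

test_that("SRI endpoints, linearity and patch-count monotonicity", {
  part <- list(nominal_area_m2 = 1e6)
  mk <- function(n_patches_per_unit) {
    purrr::imap_dfr(n_patches_per_unit, function(np, u) {
      tibble::tibble(unit = as.integer(u), patch = seq_len(np), class = 2L,
                     cells = 4L, area_m2 = 4e4, perimeter_m = 800)
    })
  }
  ind <- conflict_indices(mk(c(`1` = 2L, `2` = 6L, `3` = 10L)), part)
  expect_equal(ind$sri[ind$n_patches == 10], 0)  # most fragmented
  expect_equal(ind$sri[ind$n_patches == 2], 1)   # least fragmented
  expect_equal(ind$sri[ind$n_patches == 6], 0.5) # midway PD
  # adding a patch to one unit never increases its SRI
  ind2 <- conflict_indices(mk(c(`1` = 2L, `2` = 7L, `3` = 10L)), part)
  expect_lte(ind2$sri[ind2$unit == 2], ind$sri[ind$unit == 2])
  # no contrast: SRI defined as 1 for all units
  expect_message(ind3 <- conflict_indices(mk(c(`1` = 3L, `2` = 3L)), part),
                 "contrast")
  expect_equal(ind3$sri, c(1, 1))
})

test_that("SCCI normalization, level bins and affine invariance", {
  units <- tibble::tibble(sci = c(1.0, 1.2, 1.5, 2.0),
                          svi = c(1, 2, 3, 4),
                          sri = c(1, 0.5, 0.2, 0))
  out <- scci(units)
  expect_equal(out$scci_raw, units$sci + units$svi - units$sri)
  expect_equal(min(out$scci_norm), 0)
  expect_equal(max(out$scci_norm), 1)
  expect_equal(out$level[which.min(out$scci_norm)], 1L)
  expect_equal(out$level[which.max(out$scci_norm)], 5L)
  expect_true(all(out$level %in% 1:5))
  # affine rescaling of the raw pool leaves the normalized index unchanged
  shifted <- scci(dplyr::mutate(units, sci = 3 * sci + 7, svi = 3 * svi,
                                sri = 3 * sri))
  expect_equal(shifted$scci_norm, out$scci_norm)
  # degenerate pool
  expect_message(deg <- scci(tibble::tibble(sci = c(1, 1), svi = c(1, 1),
                                            sri = c(0, 0))), "degenerate")
  expect_equal(deg$scci_norm, c(0, 0))
})

test_that("level bins are half-open with a closed top bin", {
  units <- tibble::tibble(scci_norm = c(0, 0.199, 0.2, 0.4, 0.6, 0.799,
                                        0.8, 1.0))
  lev <- pmin(5L, findInterval(units$scci_norm, c(0, 0.2, 0.4, 0.6, 0.8)))
  expect_equal(lev, c(1L, 1L, 2L, 3L, 4L, 4L, 5L, 5L))
})

test_that("summaries reproduce published percentage arithmetic", {
  # level shares for the published 2005 unit counts (16/217/1009/877/74
  # of 2193) and the 2020 stronger-conflict count (145 of 2193)
  fake <- structure(list(
    units = tibble::tibble(
      date = c(rep("2005", 2193), rep("2020", 2193)),
      level = c(rep(1:5, times = c(16, 217, 1009, 877, 74)),
                rep(1:5, times = c(14, 202, 897, 935, 145))),
      dominant_ple = "PE"),
    partition = list(n_units = 2193)), class = "conflict_result")
  s05 <- summarize_conflict(fake)
  expect_equal(round(s05$pct[s05$date == "2005"], 2),
               c(0.73, 9.90, 46.01, 39.99, 3.37))
  expect_equal(round(s05$pct[s05$date == "2020" & s05$level == 5], 2), 6.61)
  r <- random_ple_raster(40, cell_size = 100, seed = 5)
  res <- conflict_assess(list(`2020` = r), unit_size = 1000)
  s <- summarize_conflict(res)
  expect_equal(sum(s$n_units), res$partition$n_units)
  expect_equal(sum(s$pct), 100)
  ct <- conflict_crosstab(res)
  expect_equal(sum(ct$pct), 100)
  expect_equal(sum(ct$n_units), res$partition$n_units)
})

test_that("full assessment equals the brute-force route on a random raster", {
  r <- random_ple_raster(50, cell_size = 100, seed = 7)
  res <- conflict_assess(list(d = r), unit_size = 1000)
  part <- res$partition
  A <- part$nominal_area_m2
  w <- vulnerability_weights()[names(ple_classes())]
  # independent per-unit recomputation from first principles
  ref <- purrr::map_dfr(part$units$unit, function(u) {
    sel <- part$unit_id == u
    sub <- r$values
    sub[!sel] <- NA_integer_
    rows <- range(which(rowSums(sel) > 0)); cols <- range(which(colSums(sel) > 0))
    sub <- sub[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
    lab <- flood_fill_label(sub, 8)
    areas <- tabulate(lab) * r$cell_size^2
    per <- brute_perimeter(sub, lab, r$cell_size)
    cls <- vapply(seq_len(max(lab)),
                  function(p) sub[which(lab == p)[1]], 1L)
    tibble::tibble(
      unit = u,
      sci = sum(2 * log(0.25 * per) / log(areas) * areas / A),
      svi = sum(w[cls] * areas) / A,
      pd = max(lab) / A)
  })
  ref$sri <- 1 - (ref$pd - min(ref$pd)) / (max(ref$pd) - min(ref$pd))
  got <- res$units[match(ref$unit, res$units$unit), ]
  expect_equal(got$sci, ref$sci)
  expect_equal(got$svi, ref$svi)
  expect_equal(got$sri, ref$sri)
})

test_that("joint and per-date pools are both available and consistent", {
  r1 <- random_ple_raster(30, cell_size = 100, seed = 8)
  r2 <- random_ple_raster(30, cell_size = 100, seed = 9)
  joint <- conflict_assess(list(a = r1, b = r2), pool = "joint")
  per <- conflict_assess(list(a = r1, b = r2), pool = "per_date")
  # per-date pools attain both endpoints within each date
  for (d in c("a", "b")) {
    expect_equal(min(per$units$scci_norm[per$units$date == d]), 0)
    expect_equal(max(per$units$scci_norm[per$units$date == d]), 1)
  }
  # joint pool: one global min and max
  expect_equal(min(joint$units$scci_norm), 0)
  expect_equal(max(joint$units$scci_norm), 1)
  # raw indices identical under either pooling
  expect_equal(joint$units$scci_raw[order(joint$units$date, joint$units$unit)],
               per$units$scci_raw[order(per$units$date, per$units$unit)])
})
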
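# Damage statistics: ensemble records, PDFs, threshold classification,
# exposure counting, CDI closed forms, residence times, damage maps.

test_that("classify_damaged counts per-cell peaks against thresholds", {
  # 10 cells, 3 with peak L/L0 >= 2 -> 30%
  rec <- synthetic_records(10L)
  rec$length_ratio <- 1.0
  rec$length_ratio[rec$cell_id %in% c(2, 5, 9) & rec$time == rec$time[3]] <- 2.4
  out <- classify_damaged(rec, damage_criteria(elongation = 2,
                                               shear_strain = 3,
                                               area_increment = 0.12))
  el <- out[out$criterion == "elongation", ]
  expect_equal(el$damaged_pct, 30)
  expect_identical(el$damaged_cells, 3L)
  # a threshold below every observation flags 100%
  out2 <- classify_damaged(rec, damage_criteria(elongation = 0.5,
                                                shear_strain = 0.5,
                                                area_increment = 0.001))
  expect_true(all(out2$damaged_pct[out2$criterion == "elongation"] == 100))
})

test_that("damaged fractions equal a brute-force recount on random cohorts", {
  rec <- synthetic_records(25L, seed = 7L)
  crit <- damage_criteria()
  out <- classify_damaged(rec, crit)
  for (cr in c("elongation", "shear_strain", "area_increment")) {
    q <- switch(cr, elongation = rec$length_ratio,
                shear_strain = rec$mean_shear_strain,
                area_increment = rec$area_ratio - 1)
    for (th in crit[[cr]]) {
      brute <- 0L
      for (cid in unique(rec$cell_id)) {
        if (max(q[rec$cell_id == cid]) >= th) brute <- brute + 1L
      }
      got <- out$damaged_cells[out$criterion == cr & out$threshold == th]
      expect_identical(got, brute)
    }
  }
  # monotone non-increasing in the threshold
  for (cr in unique(out$criterion)) {
    d <- out$damaged_pct[out$criterion == cr]
    expect_true(all(diff(d) <= 0))
  }
})

test_that("instances per damaged cell: counting convention and brute force", {
  rec <- synthetic_records(6L, n_times = 10L, seed = 1L)
  rec$length_ratio <- 1
  rec$length_ratio[rec$cell_id == 3][1:5] <- 2.5 # one damaged cell, 5 instances
  out <- instances_per_damaged(rec, damage_criteria(elongation = 2,
                                                    shear_strain = 3,
                                                    area_increment = 0.12))
  expect_equal(out$mean_instances[out$criterion == "elongation"], 5)
  # no damaged cells: absent (NA), not zero
  rec$length_ratio <- 1
  out0 <- instances_per_damaged(rec, damage_criteria(elongation = 2,
                                                     shear_strain = 1e6,
                                                     area_increment = 1e6))
  expect_true(all(is.na(out0$mean_instances)))
  # brute force on a random cohort
  rec2 <- synthetic_records(15L, seed = 3L)
  crit <- damage_criteria()
  out2 <- instances_per_damaged(rec2, crit)
  q <- rec2$mean_shear_strain
  th <- crit$shear_strain[2]
  counts <- vapply(unique(rec2$cell_id), function(cid) {
    sum(q[rec2$cell_id == cid] >= th)
  }, numeric(1))
  brute <- mean(counts[counts > 0])
  got <- out2$mean_instances[out2$criterion == "shear_strain" &
                               out2$threshold == th]
  expect_equal(got, brute)
})

test_that("cell damage index closed forms", {
  # one cell, A/A0 = 1.1 constant over 1 s
  rec <- tibble::tibble(cell_id = 1L, time = seq(0, 0.999, by = 1e-3),
                        dt_i = 1e-3, area_ratio = 1.1, length_ratio = 1.05,
                        mean_shear_strain = 1.2)
  expect_equal(cell_damage_index(rec, alpha = 1, metric = "area")$cdi, 0.1,
               tolerance = 1e-12)
  expect_equal(cell_damage_index(rec, alpha = 2, metric = "area")$cdi, 0.01,
               tolerance = 1e-12)
  # two cells: excess 0.1 for 1 s and excess 0 -> mean 0.05
  rec2 <- dplyr::bind_rows(rec, dplyr::mutate(rec, cell_id = 2L, area_ratio = 1))
  expect_equal(cell_damage_index(rec2, alpha = 1, metric = "area")$cdi, 0.05,
               tolerance = 1e-12)
  # homogeneity: scaling all dt by c scales CDI by c
  rec3 <- dplyr::mutate(rec2, dt_i = dt_i * 3.5)
  expect_equal(cell_damage_index(rec3, 1, "area")$cdi,
               3.5 * cell_damage_index(rec2, 1, "area")$cdi, tolerance = 1e-12)
  # binary-excess cohort: CDI(alpha) = e^alpha * exceeding time / n_cells
  set.seed(12)
  e <- 0.3
  recb <- synthetic_records(8L, n_times = 30L, seed = 12L)
  on <- stats::runif(nrow(recb)) < 0.4
  recb$area_ratio <- 1 + ifelse(on, e, 0)
  for (al in c(1, 2, 3.5)) {
    expected <- e^al * sum(recb$dt_i[on]) / 8
    expect_equal(cell_damage_index(recb, al, "area")$cdi, expected,
                 tolerance = 1e-12)
  }
  # alpha < 1 rejected; absolute value applied to negative excursions
  expect_error(cell_damage_index(rec, alpha = 0.5), "alpha")
  recn <- dplyr::mutate(rec, area_ratio = 0.9)
  expect_equal(cell_damage_index(recn, 1, "area")$cdi, 0.1, tolerance = 1e-12)
})

test_that("strain PDFs normalize to one and respect the shear lower bound", {
  rec <- synthetic_records(12L)
  pdfs <- strain_pdfs(rec, bins = 60L)
  for (mv in unique(pdfs$measure)) {
    d <- pdfs[pdfs$measure == mv, ]
    width <- diff(d$bin_mid[1:2])
    expect_equal(sum(d$density * width), 1, tolerance = 1e-10)
  }
  sh <- pdfs[pdfs$measure %in% c("max_shear_strain", "mean_shear_strain"), ]
  expect_true(all(sh$bin_mid[sh$density > 0] >= 1))
  # single record: delta-like PDF, still integral 1
  p1 <- strain_pdfs(rec[1, ], bins = 10L)
  d1 <- p1[p1$measure == "area_ratio", ]
  expect_equal(sum(d1$density * diff(d1$bin_mid[1:2])), 1, tolerance = 1e-8)
  # histogram of a known generator matches its density within sampling error
  set.seed(99)
  recu <- synthetic_records(40L, n_times = 50L, seed = 99L)
  recu$DI <- stats::runif(nrow(recu)) # exercise a uniform target
  pu <- strain_pdfs(dplyr::mutate(recu, max_areal_strain = DI + 1), bins = 10L)
  du <- pu[pu$measure == "max_areal_strain", ]
  expect_lt(max(abs(du$density - 1)), 0.2) # uniform density 1 on [1, 2]
})

test_that("summarize_cell flattens a simulation and checks the time base", {
  mat <- table1_material()
  ref <- make_reference(rbc_a, 0.9)
  s <- make_resting_rbc(rbc_a, order = 8L)
  h <- far_field_history(c(0, 1), matrix(0, 2, 3), matrix(0, 2, 9))
  res <- advance_cell(s, ref, mat, h, dt = 2e-6, t_end = 4e-5, record_stride = 5L)
  rec <- summarize_cell(res)
  expect_true(all(rec$max_areal_strain >= rec$mean_areal_strain - 1e-12))
  expect_true(all(rec$max_shear_strain >= rec$mean_shear_strain - 1e-12))
  expect_true(all(rec$mean_shear_strain >= 1))
  expect_true(all(rec$dt_i > 0))
  # resting biconcave vs oblate reference: strains do not start at 1
  expect_gt(rec$mean_areal_strain[1], 1.1)
  bad <- tibble::tibble(time = rec$time + 1, gdot = 0)
  expect_error(summarize_cell(res, trajectory = bad), "time base")
})

test_that("uniformly inflated sphere: max equals mean areal strain", {
  ref <- make_reference(rbc_a, 1)
  s <- rbcflow:::reference_surface(ref, order = 8L)
  s$coefficients <- s$coefficients * 1.1
  st <- principal_stretches(s, ref)
  w <- st$area_weight / sum(st$area_weight)
  expect_equal(max(st$areal_strain), 1.21, tolerance = 1e-8)
  expect_equal(sum(w * st$areal_strain), 1.21, tolerance = 1e-8)
  # synthetic strain fields: max/mean match a brute-force scan
  vals <- st$areal_strain + sin(seq_along(st$areal_strain))^2
  expect_equal(max(vals), sort(vals, decreasing = TRUE)[1])
})

test_that("residence time: closed forms", {
  m <- steady_pipe()
  U <- 0.25
  mu <- m; mu$frames <- list(matrix(c(0, 0, U), nrow(m$nodes), 3, byrow = TRUE))
  mu <- project_gradients(mu)
  x0 <- rbind(c(0, 0, 1e-5), c(2e-4, 0, 1e-5))
  dt <- 1e-4
  tr <- advect(mu, x0, dt = dt, t_end = 0.1, record_stride = 1L)
  rt <- residence_time(tr)
  expect_equal(rt$mean_residence, m$length / U, tolerance = dt / (m$length / U) * 2)
  # two particles with known dwell times -> arithmetic mean
  fake <- tr
  fake$history <- tibble::tibble(
    particle = c(1L, 1L, 1L, 2L), time = c(0, 1, 2, 0) * 1e-3,
    x = 0, y = 0, z = 0
  )
  fake$dt <- 1e-3
  expect_equal(residence_time(fake)$mean_residence,
               mean(c(3e-3, 1e-3)), tolerance = 1e-12)
})

test_that("damage maps carry metrics onto path-line vertices and round-trip", {
  rec <- synthetic_records(3L, n_times = 5L)
  traj <- list(history = tibble::tibble(
    particle = rec$cell_id, time = rec$time,
    x = stats::runif(nrow(rec)), y = stats::runif(nrow(rec)), z = stats::runif(nrow(rec))
  ))
  class(traj) <- "particle_trajectories"
  dm <- damage_map(traj, rec, metric = "mean_shear_strain")
  expect_identical(nrow(dm), nrow(rec))
  chk <- dplyr::inner_join(dm, rec, by = c("cell_id", "time"))
  expect_equal(chk$value, chk$mean_shear_strain, tolerance = 1e-12)
  # constant metric -> uniformly colored line
  rec$mean_shear_strain <- 2.2
  dm2 <- damage_map(traj, rec)
  expect_true(all(dm2$value == 2.2))
  # VTK write/read round trip preserves scalars bit-exactly
  f <- tempfile(fileext = ".vtk")
  write_pathlines_vtk(dm2, f)
  ln <- readLines(f)
  i <- grep("LOOKUP_TABLE default", ln)[1]
  vals <- as.numeric(ln[(i + 1):(i + nrow(dm2))])
  expect_identical(vals, dm2$value)
  # a metric spike colors a single vertex
  rec$mean_shear_strain[7] <- 9.9
  dm3 <- damage_map(traj, rec)
  expect_identical(sum(dm3$value > 9), 1L)
})

test_that("damage_report bundles tables and tidy/glance work", {
  rec <- synthetic_records(10L)
  rep <- damage_report(rec, alpha = c(1, 2))
  td <- tidy(rep)
  expect_true(all(c("criterion", "threshold", "damaged_pct", "mean_instances")
                  %in% names(td)))
  gl <- glance(rep)
  expect_identical(gl$n_cells, 10L)
  expect_s3_class(autoplot(rep), "ggplot")
})
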
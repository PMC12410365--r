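# Ensemble damage statistics over cell-resolved results: deformation
# records, strain PDFs, threshold classification, exposure counting, the
# cell damage index (CDI), residence times and path-line damage maps.
# Every record surface is a tibble so results chain with dplyr.

#' Deformation records of a simulated cell
#'
#' Flattens an [advance_cell()] result into the per-(cell, time) ensemble
#' records that feed all damage statistics: each output time of each cell is
#' one ensemble member.
#'
#' @param result an [advance_cell()] result.
#' @param trajectory optional `particle_trajectories` history rows for this
#'   cell (same time base) whose `gdot` column overrides the far-field one.
#' @return a tibble with columns `cell_id`, `time`, `dt_i` (time weight, s),
#'   `max_areal_strain`, `mean_areal_strain`, `max_shear_strain`,
#'   `mean_shear_strain`, `area_ratio` (A/A0), `length_ratio` (L/L0), `DI`,
#'   `gdot` (1/s). A0 and L0 are the resting-shape area and length.
#' @export
summarize_cell <- function(result, trajectory = NULL) {
  stopifnot(inherits(result, "rbc_sim_result"))
  r <- result$records
  if (!is.null(trajectory)) {
    tr <- if (inherits(trajectory, "particle_trajectories")) trajectory$history else trajectory
    if (nrow(tr) != nrow(r) || max(abs(tr$time - r$time)) > 1e-12 + 1e-6 * max(r$time)) {
      stop("trajectory and simulation result do not share a time base", call. = FALSE)
    }
    gdot <- tr$gdot
  } else {
    gdot <- r$shear_rate
  }
  dt_i <- c(diff(r$time), if (nrow(r) > 1L) diff(r$time)[nrow(r) - 1L] else result$dt)
  tibble::tibble(
    cell_id = r$cell_id, time = r$time, dt_i = dt_i,
    max_areal_strain = r$max_areal_strain,
    mean_areal_strain = r$mean_areal_strain,
    max_shear_strain = r$max_shear_strain,
    mean_shear_strain = r$mean_shear_strain,
    area_ratio = r$area_ratio, length_ratio = r$length_ratio,
    DI = r$DI, gdot = gdot
  )
}

#' Damage criteria thresholds
#'
#' Literature-derived critical values for mechanical RBC damage: elongation
#' ratios L/L0, mean shear strains `lambda1/lambda2`, and relative area
#' increments A/A0 - 1.
#'
#' @param elongation critical `L/L0` thresholds (default `c(1.75, 2, 2.25)`).
#' @param shear_strain critical mean shear strains (default
#'   `c(2.5, 3.0, 3.5)`).
#' @param area_increment critical relative area increases (default
#'   `c(0.10, 0.12, 0.14)`).
#' @return an object of class `damage_criteria`.
#' @export
damage_criteria <- function(elongation = c(1.75, 2, 2.25),
                            shear_strain = c(2.5, 3.0, 3.5),
                            area_increment = c(0.10, 0.12, 0.14)) {
  chk <- function(x) is.numeric(x) && all(x > 0) && !is.unsorted(x)
  if (!chk(elongation) || !chk(shear_strain) || !chk(area_increment)) {
    stop("thresholds must be positive and sorted ascending", call. = FALSE)
  }
  structure(list(elongation = elongation, shear_strain = shear_strain,
                 area_increment = area_increment),
            class = "damage_criteria")
}

# criterion quantity extracted from records (per instant)
criterion_value <- function(records, criterion) {
  switch(criterion,
    elongation = records$length_ratio,
    shear_strain = records$mean_shear_strain,
    area_increment = records$area_ratio - 1,
    stop("unknown criterion: ", criterion, call. = FALSE)
  )
}

#' Strain probability density functions
#'
#' Normalized histograms (integral one) of the six ensemble deformation
#' measures: maximum and mean areal/shear strains, normalized area and
#' normalized length, pooling all cells and times (each (cell, time) pair is
#' one ensemble member).
#'
#' @param records a [summarize_cell()] tibble (rows from many cells).
#' @param bins number of uniform bins (default 200) or a list of explicit
#'   break vectors per measure.
#' @return a tibble with `measure`, `bin_mid`, `density`, `count`.
#' @export
strain_pdfs <- function(records, bins = 200L) {
  measures <- c("max_areal_strain", "max_shear_strain", "mean_areal_strain",
                "mean_shear_strain", "area_ratio", "length_ratio")
  purrr::map_dfr(measures, function(mv) {
    x <- records[[mv]]
    x <- x[is.finite(x)]
    brk <- if (is.list(bins)) bins[[mv]] else {
      rng <- range(x)
      if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5) * max(abs(rng[1]) * 1e-6, 1e-12)
      seq(rng[1], rng[2], length.out = bins + 1L)
    }
    h <- graphics::hist(x, breaks = brk, plot = FALSE)
    tibble::tibble(measure = mv, bin_mid = h$mids, density = h$density,
                   count = h$counts)
  })
}

#' Classify damaged cells
#'
#' A cell is damaged under a (criterion, threshold) pair when its per-cell
#' peak of the criterion quantity meets or exceeds the threshold; the
#' damaged fraction is reported as a percentage of all cells.
#'
#' @param records a [summarize_cell()] tibble covering all cells.
#' @param criteria a [damage_criteria()].
#' @return a tibble with `criterion`, `threshold`, `damaged_cells`,
#'   `total_cells`, `damaged_pct`.
#' @export
classify_damaged <- function(records, criteria = damage_criteria()) {
  total <- dplyr::n_distinct(records$cell_id)
  purrr::map_dfr(c("elongation", "shear_strain", "area_increment"), function(cr) {
    peaks <- records %>%
      dplyr::mutate(.q = criterion_value(records, cr)) %>%
      dplyr::group_by(.data$cell_id) %>%
      dplyr::summarise(peak = max(.data$.q), .groups = "drop")
    purrr::map_dfr(criteria[[cr]], function(th) {
      nd <- sum(peaks$peak >= th)
      tibble::tibble(criterion = cr, threshold = th, damaged_cells = nd,
                     total_cells = total, damaged_pct = 100 * nd / total)
    })
  })
}

#' Exposure instances per damaged cell
#'
#' For each damaged cell (per-cell peak exceeding the threshold), counts the
#' recorded instances at or above the threshold; reports the mean count over
#' damaged cells, or `NA` when no cell is damaged.
#'
#' @inheritParams classify_damaged
#' @return a tibble with `criterion`, `threshold`, `mean_instances`.
#' @export
instances_per_damaged <- function(records, criteria = damage_criteria()) {
  purrr::map_dfr(c("elongation", "shear_strain", "area_increment"), function(cr) {
    q <- criterion_value(records, cr)
    purrr::map_dfr(criteria[[cr]], function(th) {
      per_cell <- records %>%
        dplyr::mutate(.exceed = q >= th) %>%
        dplyr::group_by(.data$cell_id) %>%
        dplyr::summarise(n_exceed = sum(.exceed), .groups = "drop") %>%
        dplyr::filter(.data$n_exceed > 0L)
      tibble::tibble(criterion = cr, threshold = th,
                     mean_instances = if (nrow(per_cell)) mean(per_cell$n_exceed)
                     else NA_real_)
    })
  })
}

#' Cell damage index
#'
#' Time-weighted power-law accumulation of a deformation excess over the
#' cohort,
#' \deqn{CDI = \frac{1}{n_{RBC}} \sum_{cells} \sum_{times}
#'   |e_i|^\alpha \, \Delta t_i,}
#' with excess `e` equal to `(A - A0)/A0` (`"area"`), `(L - L0)/L0`
#' (`"elongation"`), or `lambda1/lambda2 - 1` (`"shear"`); the exponent
#' `alpha >= 1` weights extreme events (absolute value is applied, so
#' excursions below baseline also accumulate).
#'
#' @param records a [summarize_cell()] tibble with `dt_i` time weights.
#' @param alpha exponent(s), each `>= 1`.
#' @param metric one or more of `"area"`, `"elongation"`, `"shear"`.
#' @return a tibble with `metric`, `alpha`, `cdi`.
#' @export
cell_damage_index <- function(records, alpha = 1, metric = c("area", "elongation", "shear")) {
  metric <- match.arg(metric, several.ok = TRUE)
  if (any(alpha < 1)) stop("alpha must be >= 1", call. = FALSE)
  n_cells <- dplyr::n_distinct(records$cell_id)
  purrr::map_dfr(metric, function(mt) {
    e <- switch(mt,
      area = records$area_ratio - 1,
      elongation = records$length_ratio - 1,
      shear = records$mean_shear_strain - 1
    )
    purrr::map_dfr(alpha, function(al) {
      tibble::tibble(metric = mt, alpha = al,
                     cdi = sum(abs(e)^al * records$dt_i) / n_cells)
    })
  })
}

#' Mean residence time
#'
#' Mean over particles of the time spent in the domain (or in a tagged
#' element subset when `region_elements` is given) before exit.
#'
#' @param trajectories a [advect()] result.
#' @param region_elements optional integer vector of element ids defining
#'   the region of interest; residence then counts only samples whose host
#'   lies in the region.
#' @param index optional [build_search_index()] used to re-locate hosts when
#'   a region is requested.
#' @param field the flow field (required with `region_elements`).
#' @return list with `mean_residence`, s, and the per-particle tibble.
#' @export
residence_time <- function(trajectories, region_elements = NULL,
                           field = NULL, index = NULL) {
  h <- trajectories$history
  dt <- trajectories$dt
  if (!is.null(region_elements)) {
    if (is.null(field)) stop("`field` needed to locate region entries", call. = FALSE)
    if (is.null(index)) index <- build_search_index(field)
    hosts <- locate_host(cbind(h$x, h$y, h$z), index)
    h <- h[hosts %in% region_elements, , drop = FALSE]
  }
  per <- h %>%
    dplyr::group_by(particle = .data$particle) %>%
    dplyr::summarise(t_in = min(.data$time), t_out = max(.data$time) + dt,
                     residence = .data$t_out - .data$t_in, .groups = "drop")
  list(mean_residence = mean(per$residence), per_particle = per)
}

#' Path-line damage map payload
#'
#' Joins trajectory vertices with per-time deformation records so each
#' path-line vertex carries the chosen damage metric as a scalar; suitable
#' for writing as coloured VTK polylines (a common colour scale across runs
#' is just a shared `limits` choice downstream).
#'
#' @param trajectories an [advect()] result (positions required).
#' @param records a [summarize_cell()] tibble whose `cell_id` matches the
#'   trajectory particle ids.
#' @param metric records column to map onto the path line (default
#'   `"mean_shear_strain"`).
#' @return a tibble `cell_id`, `time`, `x`, `y`, `z`, `value`.
#' @export
damage_map <- function(trajectories, records, metric = "mean_shear_strain") {
  if (!metric %in% names(records)) stop("unknown metric column: ", metric, call. = FALSE)
  h <- trajectories$history %>%
    dplyr::select(cell_id = "particle", "time", "x", "y", "z")
  rec <- records %>% dplyr::select("cell_id", "time", value = dplyr::all_of(metric))
  dplyr::inner_join(h, rec, by = c("cell_id", "time"))
}

#' Full damage report
#'
#' Bundles the Table-style summaries for a cohort of deformation records:
#' damaged fractions per criterion/threshold, mean exposure instances per
#' damaged cell, CDI values over a grid of exponents, and the strain PDFs.
#'
#' @param records pooled [summarize_cell()] records.
#' @param criteria a [damage_criteria()].
#' @param alpha CDI exponents (default `c(1, 2, 3, 4)`).
#' @param bins PDF bins.
#' @param mean_residence optional mean residence time, s, carried through.
#' @param n_unstable number of excluded unstable cells (bookkeeping).
#' @return an object of class `damage_report`.
#' @export
damage_report <- function(records, criteria = damage_criteria(),
                          alpha = c(1, 2, 3, 4), bins = 200L,
                          mean_residence = NA_real_, n_unstable = 0L) {
  structure(
    list(
      fractions = classify_damaged(records, criteria),
      instances = instances_per_damaged(records, criteria),
      cdi = cell_damage_index(records, alpha = alpha,
                              metric = c("area", "elongation", "shear")),
      pdfs = strain_pdfs(records, bins = bins),
      mean_residence = mean_residence,
      n_cells = dplyr::n_distinct(records$cell_id),
      n_records = nrow(records),
      n_unstable = n_unstable,
      criteria = criteria
    ),
    class = "damage_report"
  )
}

#' @export
print.damage_report <- function(x, ...) {
  cat(sprintf("<damage_report> %d cells, %d ensemble records (%d unstable excluded)\n",
              x$n_cells, x$n_records, x$n_unstable))
  print(as.data.frame(x$fractions), digits = 3)
  invisible(x)
}

#' @rdname damage_report
#' @param x a `damage_report`.
#' @export
tidy.damage_report <- function(x, ...) {
  dplyr::left_join(x$fractions, x$instances, by = c("criterion", "threshold"))
}

#' @rdname damage_report
#' @export
glance.damage_report <- function(x, ...) {
  tibble::tibble(
    n_cells = x$n_cells, n_records = x$n_records, n_unstable = x$n_unstable,
    mean_residence = x$mean_residence,
    worst_fraction_pct = max(x$fractions$damaged_pct),
    cdi_area_alpha1 = x$cdi$cdi[x$cdi$metric == "area" & x$cdi$alpha == 1][1]
  )
}

#' @export
tidy.rbc_sim_result <- function(x, ...) x$records

#' @export
glance.rbc_sim_result <- function(x, ...) {
  r <- x$records; n <- nrow(r)
  tibble::tibble(
    stability = x$stability,
    t_end = r$time[n],
    volume_drift = abs(r$volume[n] / r$volume[1] - 1),
    peak_length_ratio = max(r$length_ratio),
    peak_area_ratio = max(r$area_ratio),
    peak_max_shear_strain = max(r$max_shear_strain),
    peak_Ca = max(r$Ca)
  )
}

#' Plot strain PDFs
#'
#' @param object a [damage_report()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.damage_report <- function(object, ...) {
  ggplot2::ggplot(object$pdfs,
                  ggplot2::aes(x = .data$bin_mid, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~measure, scales = "free") +
    ggplot2::labs(x = "value", y = "probability density",
                  title = "Deformation ensemble PDFs")
}

#' Plot a cell simulation's deformation history
#'
#' @param object an [advance_cell()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.rbc_sim_result <- function(object, ...) {
  r <- object$records %>%
    dplyr::select("time", "area_ratio", "length_ratio",
                  "max_areal_strain", "max_shear_strain") %>%
    tidyr::pivot_longer(-"time")
  ggplot2::ggplot(r, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~name, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
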
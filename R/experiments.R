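#' Load schedule of the standing-load experiment
#'
#' Six vertical force magnitudes from 50 N to 550 N in 100 N intervals,
#' applied downwards onto the lumbar top face.
#'
#' @param magnitudes strictly increasing positive force magnitudes in N.
#' @param direction unit load direction (default vertical down, -y).
#' @return object of class `load_schedule`.
#' @export
load_schedule <- function(magnitudes = c(50, 150, 250, 350, 450, 550),
                          direction = c(0, -1, 0)) {
  stopifnot(length(magnitudes) >= 1, all(magnitudes > 0),
            all(diff(magnitudes) > 0), length(direction) == 3L)
  direction <- direction / sqrt(sum(direction^2))
  structure(list(magnitudes = magnitudes, direction = direction),
            class = "load_schedule")
}

#' Strain measurement point
#'
#' @param label point label (1-7 in the reference protocol).
#' @param position probe centre in mm.
#' @param radius probe radius in mm (> 0).
#' @return object of class `measurement_point`.
#' @export
measurement_point <- function(label, position, radius) {
  stopifnot(length(position) == 3L, radius > 0)
  structure(list(label = label, position = as.double(position),
                 radius = radius), class = "measurement_point")
}

#' Default measurement points on the phantom
#'
#' The seven anatomical probe locations of the reference protocol (midpoint
#' of the iliopectineal line; acetabular inner plate; first sacral vertebra
#' near the sacroiliac joint; ilium at sacral height; iliac fossa; ischial
#' notch; posterior ilium near the sacroiliac joint) mapped to the phantom's
#' homologous coordinates.  The probe radius defaults to twice the mean
#' element edge length.
#'
#' @param model a [phantom_model].
#' @param radius probe radius in mm; default `2 * mean_edge_length(model$mesh)`.
#' @return list of [measurement_point] objects.
#' @export
default_measurement_points <- function(model, radius = NULL) {
  sp <- model$spec
  S <- sp$overall_scale; g <- sp$cartilage_gap
  w <- (S - 3 * g) / 4; h <- S / 7; d <- S / 4
  E <- cumsum(c(0, w, g, w, g, w, g, w))
  Y <- seq(0, S, by = h)
  if (is.null(radius)) radius <- 2 * mean_edge_length(model$mesh)
  pos <- list(
    `1` = c((E[2] + E[3]) / 2, (Y[2] + Y[3]) / 2, d / 2),
    `2` = c(w / 2, Y[2] + h / 4, d / 2),
    `3` = c(E[4] + w / 8, (Y[5] + Y[6]) / 2, d / 2),
    `4` = c(w / 2, (Y[5] + Y[6]) / 2, d / 2),
    `5` = c(w / 2, (Y[4] + Y[5]) / 2, d / 2),
    `6` = c(w / 2, (Y[3] + Y[4]) / 2, d / 2),
    `7` = c(w / 2, (Y[5] + Y[6]) / 2, 3 * d / 4))
  lapply(names(pos), function(nm) measurement_point(as.integer(nm), pos[[nm]], radius))
}

mean_edge_length <- function(mesh) {
  pairs <- rbind(mesh$tets[, c(1, 2)], mesh$tets[, c(1, 3)], mesh$tets[, c(1, 4)],
                 mesh$tets[, c(2, 3)], mesh$tets[, c(2, 4)], mesh$tets[, c(3, 4)])
  mean(sqrt(rowSums((mesh$nodes[pairs[, 1], , drop = FALSE] -
                     mesh$nodes[pairs[, 2], , drop = FALSE])^2)))
}

#' Run the loading experiment on one model variant
#'
#' Applies each magnitude of the schedule as a total force on the `load_top`
#' node set (direction from the schedule), with the femora fully fixed and
#' the vertebra guide constrained to vertical motion only, solves the static
#' problem (Newton path when hyperelastic or secant cartilage elements are
#' present), and summarises max/mean von Mises stress and equivalent strain
#' over all elements and over the bone subset.  A failing step is recorded
#' as a failure annotation and later steps are still attempted.
#'
#' @param mesh an [fe_mesh] model variant.
#' @param materials a [material_field].
#' @param schedule a [load_schedule].
#' @param config a `run_config` (solver controls).
#' @param keep_solutions keep the full per-step solution fields (needed for
#'   probing); default `TRUE`.
#' @return object of class `loading_report`: tibble `summaries` (one row per
#'   magnitude and subset), `solutions`, `failures`, `schedule`.
#' @export
run_loading_experiment <- function(mesh, materials, schedule = load_schedule(),
                                   config = default_run_config(),
                                   keep_solutions = TRUE) {
  bcs <- list(boundary_condition("femur_fix", c("x", "y", "z")),
              boundary_condition("vertebra_guide", c("x", "z")))
  nonlinear <- any(materials$tets$family %in% c("cartilage", "mooney_rivlin"))
  system <- if (!nonlinear) fe_assemble(mesh, materials, bcs)
  rows <- list(); sols <- list(); fails <- list()
  for (mag in schedule$magnitudes) {
    ld <- load_case("load_top", mag * schedule$direction,
                    label = paste0(mag, "N"))
    sol <- tryCatch({
      if (nonlinear) {
        solve_newton(mesh, materials, bcs, list(ld),
                     steps = config$solver$steps, tol = config$solver$tol,
                     max_iter = config$solver$max_iter)
      } else {
        solve_linear(system, list(ld))
      }
    }, error = function(e) e)
    if (inherits(sol, "error")) {
      fails[[as.character(mag)]] <- conditionMessage(sol)
      next
    }
    pp <- postprocess(sol)
    s <- pp$summaries
    s$load <- mag
    rows[[as.character(mag)]] <- s[, c("load", setdiff(names(s), "load"))]
    if (keep_solutions) sols[[as.character(mag)]] <- sol
  }
  structure(list(summaries = if (length(rows)) do.call(rbind, rows) else NULL,
                 solutions = sols, failures = fails, schedule = schedule),
            class = "loading_report")
}

report_summaries <- function(x, subset = "all") {
  if (inherits(x, "loading_report")) x <- x$summaries
  x <- tibble::as_tibble(x)
  if ("subset" %in% names(x)) x <- x[x$subset == subset, setdiff(names(x), "subset")]
  x
}

#' Compare the bone-only and integrated models
#'
#' Per load step and per quantity, the percentage reduction
#' `(I - II) / I * 100` and the ratio `I / II` of the model-I value over the
#' model-II value.  Accepts full `loading_report`s or plain tibbles with a
#' `load` column and numeric summary columns (so printed literature summaries
#' can be compared directly).
#'
#' @param report_I,report_II reports (or summary tibbles) for Model I
#'   (bone only, tied joints) and Model II (integrated).
#' @param subset summary subset to compare when full reports are given.
#' @return tibble: load, quantity, model_I, model_II, reduction_pct, ratio.
#' @export
compare_models <- function(report_I, report_II, subset = "all") {
  a <- report_summaries(report_I, subset)
  b <- report_summaries(report_II, subset)
  if (!"load" %in% names(a) || !"load" %in% names(b))
    stop("summaries need a 'load' column")
  if (nrow(a) != nrow(b) || any(a$load != b$load))
    stop("mismatched load schedules between the two reports")
  qty <- intersect(names(a)[vapply(a, is.numeric, logical(1))],
                   names(b)[vapply(b, is.numeric, logical(1))])
  qty <- setdiff(qty, "load")
  out <- do.call(rbind, lapply(qty, function(q) {
    tibble::tibble(load = a$load, quantity = q,
                   model_I = a[[q]], model_II = b[[q]],
                   reduction_pct = (a[[q]] - b[[q]]) / a[[q]] * 100,
                   ratio = a[[q]] / b[[q]])
  }))
  tibble::as_tibble(out)
}

#' Probe equivalent strain at measurement points
#'
#' Volume-weighted mean equivalent elastic strain over the tetrahedra whose
#' centroids fall within each point's probe radius.
#'
#' @param solution an `fe_solution`.
#' @param points list of [measurement_point] objects.
#' @return tibble: label, x, y, z, n_elements, eq_strain.
#' @export
probe_strain <- function(solution, points) {
  mesh <- solution$mesh
  cen <- tet_centroids(mesh)
  vols <- tet_volumes(mesh)
  rows <- lapply(points, function(p) {
    d2 <- rowSums(sweep(cen, 2L, p$position)^2)
    sel <- d2 <= p$radius^2
    if (!any(sel))
      stop("measurement point ", p$label,
           ": no element centroid within radius ", p$radius, " mm")
    tibble::tibble(label = p$label, x = p$position[1L], y = p$position[2L],
                   z = p$position[3L], n_elements = sum(sel),
                   eq_strain = sum(solution$tet_eq_strain[sel] * vols[sel]) /
                     sum(vols[sel]))
  })
  do.call(rbind, rows)
}

#' Least-squares validation regression
#'
#' Ordinary least squares of model strains on reference strains
#' (`y = slope * x + intercept`), with the coefficient of determination
#' `R^2 = 1 - SS_res / SS_tot`.  By the protocol's convention `x` is the
#' reference (cadaver-experiment) strain and `y` the finite-element strain.
#'
#' @param x reference strains.
#' @param y model strains, same length, `n >= 3`.
#' @return object of class `strain_regression`: slope, intercept,
#'   `r_squared`, `n`, and the underlying `lm` fit.
#' @export
regress_validation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0) stop("reference strains have zero variance")
  fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = 1 - ss_res / ss_tot,
                 n = length(x), fit = fit),
            class = "strain_regression")
}

#' @export
print.strain_regression <- function(x, ...) {
  cat("strain regression: y = ", signif(x$slope, 6), " x + ",
      signif(x$intercept, 6), "   R^2 = ", signif(x$r_squared, 4),
      "  (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Packaged reference strain table
#'
#' The published seven-point by six-load matrix of equivalent strains
#' (mm/mm) from the integrated model's loading experiment, used as the
#' reference fixture for the validation machinery.
#'
#' @return 7 x 6 numeric matrix; rows are measurement points 1-7, columns
#'   the load magnitudes 50-550 N.
#' @export
load_reference_strains <- function() {
  tab <- utils::read.csv(system.file("extdata", "reference_strain_table.csv",
                                     package = "pelvifem"))
  m <- as.matrix(tab[, -1L])
  dimnames(m) <- list(point = tab$point,
                      load = sub("load_", "", colnames(tab)[-1L]))
  m
}

#' Run the full two-model protocol on the phantom
#'
#' Convenience driver: builds the phantom and its synthetic CT, maps
#' materials, constructs Model I (bone only, tied joints) and Model II
#' (integrated soft-tissue network, frictionless sacroiliac and acetabular
#' joints), runs the load schedule on both, tabulates reduction percentages,
#' probes the seven measurement points at the final load, and regresses the
#' probed strains against the packaged reference strains.
#'
#' @param spec a [phantom_spec].
#' @param config a `run_config`.
#' @param schedule a [load_schedule].
#' @return object of class `experiment_report`.
#' @export
run_pelvis_experiment <- function(spec = phantom_spec(),
                                  config = default_run_config(),
                                  schedule = load_schedule(
                                    config$loads$magnitudes,
                                    config$loads$direction)) {
  phantom <- make_pelvis_phantom(spec)
  ct <- rasterize_ct(phantom)
  k <- do.call(mapping_constants, config$mapping[names(config$mapping) %in%
                 names(formals(mapping_constants))])
  mats <- assign_materials(
    phantom$mesh, ct, k,
    cartilage_family = config$cartilage_family,
    cartilage = cartilage_compressive(rectified = config$cartilage_rectified))

  mesh_I <- model_I_variant(phantom$mesh)
  mesh_II <- model_II_variant(phantom$mesh,
                              joints = default_joints(config$joint_penalty))
  rep_I <- run_loading_experiment(mesh_I, mats, schedule, config)
  rep_II <- run_loading_experiment(mesh_II, mats, schedule, config)
  reductions <- compare_models(rep_I, rep_II)

  final <- as.character(max(schedule$magnitudes))
  points <- default_measurement_points(phantom)
  probes <- list()
  for (nm in c("I", "II")) {
    rep_ <- if (nm == "I") rep_I else rep_II
    if (!is.null(rep_$solutions[[final]])) {
      pr <- probe_strain(rep_$solutions[[final]], points)
      pr$model <- nm
      probes[[nm]] <- pr
    }
  }
  probes <- if (length(probes)) do.call(rbind, probes) else NULL

  reference <- load_reference_strains()
  regression <- NULL
  if (!is.null(probes) && "II" %in% probes$model) {
    y <- probes$eq_strain[probes$model == "II"]
    x <- reference[, ncol(reference)]
    regression <- regress_validation(x, y)
  }
  structure(list(spec = spec, config = config, schedule = schedule,
                 model_I = rep_I, model_II = rep_II,
                 reductions = reductions, probes = probes,
                 regression = regression),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report> loads:",
      paste(x$schedule$magnitudes, collapse = ", "), "N\n")
  if (!is.null(x$reductions)) {
    at_max <- x$reductions[x$reductions$load == max(x$reductions$load) &
                           x$reductions$quantity %in% c("max_vm", "mean_eq_strain"), ]
    print(at_max)
  }
  if (!is.null(x$regression)) print(x$regression)
  invisible(x)
}
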
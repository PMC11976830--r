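#' Potential sweep over separations
#'
#' Evaluates the integrated sphere-rod potential along a grid of radial
#' distances `rho` at fixed angle `theta`, optionally cross-checking every
#' row against the quadrature oracle.  Overlapping configurations are
#' flagged (with `NA` energy) rather than dropped, and a warning reports
#' their count.  Rows are emitted in the (deterministic) order of `rho`.
#'
#' @param a Sphere radius.
#' @param L Rod length (finite or `Inf`).
#' @param theta Polar angle of the sphere center, in `[0, pi]`.
#' @param rho Vector of radial distances from the rod end O.
#' @param lambda,rho_s Densities.
#' @param p An [lj_params()].
#' @param verify If `TRUE`, add `W_quadrature` and `rel_err` columns
#'   computed with the independent quadrature oracle.
#' @param q A [quadrature_spec()] used when `verify = TRUE`.
#' @return A tibble of class `rodsphere_sweep` with columns `rho`,
#'   `theta`, `h`, `W`, `branch`, `precision_mode`, `overlap` (and the
#'   verification columns if requested).
#' @examples
#' run_potential_sweep(a = 10, L = 5, theta = pi / 6,
#'                     rho = seq(11, 30, length.out = 20))
#' @export
run_potential_sweep <- function(a, L, theta, rho, lambda = 1, rho_s = 1,
                                p = lj_params(), verify = FALSE,
                                q = quadrature_spec()) {
  stopifnot(is.numeric(rho), length(rho) >= 1L, all(is.finite(rho)),
            theta >= 0, theta <= pi)
  s <- sphere(a, rho_s)
  r <- rod(L, lambda)
  rows <- purrr::map(rho, function(rr) {
    cfg <- local_config(rr, theta)
    if (!validate_no_overlap(cfg, s, r)) {
      out <- tibble::tibble(rho = rr, theta = theta, h = cfg$h,
                            W = NA_real_, branch = NA_character_,
                            precision_mode = NA_character_, overlap = TRUE)
      if (verify) {
        out$W_quadrature <- NA_real_
        out$rel_err <- NA_real_
      }
      return(out)
    }
    res <- finite_rod_potential(cfg, s, r, p)
    out <- tibble::tibble(rho = rr, theta = theta, h = cfg$h, W = res$W,
                          branch = res$branch,
                          precision_mode = res$precision_mode,
                          overlap = FALSE)
    if (verify) {
      wq <- as.numeric(quadrature_potential(cfg, s, r, p, q))
      out$W_quadrature <- wq
      out$rel_err <- abs(res$W - wq) / max(abs(wq), .Machine$double.xmin)
    }
    out
  })
  out <- dplyr::bind_rows(rows)
  n_over <- sum(out$overlap)
  if (n_over > 0) {
    warning(sprintf("%d overlapping configuration(s) skipped (flagged)", n_over),
            call. = FALSE)
  }
  class(out) <- c("rodsphere_sweep", class(out))
  out
}

#' Adhesion scan over a sphere-radius x rod-length grid
#'
#' Runs [find_h0()] for every combination of `a_values` and `L_values`
#' (`Inf` allowed) and returns the results as one row per combination.
#'
#' @param a_values Sphere radii.
#' @param L_values Rod lengths; `Inf` for infinite rods.
#' @param p An [lj_params()].
#' @param lambda,rho_s Densities.
#' @return A tibble of class `rodsphere_adhesion_scan` with columns `a`,
#'   `L`, `h0`, `delta_h`, `DeltaW`, `converged`.
#' @examples
#' run_adhesion_scan(c(5, 10), c(10, Inf))
#' @export
run_adhesion_scan <- function(a_values, L_values, p = lj_params(),
                              lambda = 1, rho_s = 1) {
  grid <- expand.grid(a = sort(a_values), L = sort(L_values))
  rows <- purrr::pmap(grid, function(a, L) {
    res <- find_h0(sphere(a, rho_s), rod(L, lambda), p)
    tibble::tibble(a = a, L = L, h0 = res$h0, delta_h = res$delta_h,
                   DeltaW = res$DeltaW, converged = res$converged)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("rodsphere_adhesion_scan", class(out))
  out
}

#' Batch wrench evaluation
#'
#' Computes global-frame forces and torques for a table of configurations.
#' Global input has columns `xs,ys,zs,xo,yo,zo,xl,yl,zl` (sphere center,
#' rod end O, rod end L); local input has columns `rho,theta,L` (wrenches
#' are then reported in the local frame).
#'
#' @param configs A data frame (or path readable by
#'   [read_config_table()]).
#' @param a Sphere radius.
#' @param lambda,rho_s Densities.
#' @param p An [lj_params()].
#' @param reference_point Torque reference for the rod.
#' @return The input tibble augmented with `Fx,Fy,Fz` (force on the
#'   sphere), `Tx,Ty,Tz` (torque on the rod), `ref_point` and `frame`.
#' @export
run_wrench_batch <- function(configs, a, lambda = 1, rho_s = 1,
                             p = lj_params(),
                             reference_point = c("rod_center", "rod_end_O")) {
  reference_point <- match.arg(reference_point)
  if (is.character(configs)) configs <- read_config_table(configs)
  configs <- tibble::as_tibble(configs)
  s <- sphere(a, rho_s)
  global_cols <- c("xs", "ys", "zs", "xo", "yo", "zo", "xl", "yl", "zl")
  if (all(global_cols %in% names(configs))) {
    rows <- purrr::pmap(configs[global_cols], function(xs, ys, zs, xo, yo, zo,
                                                       xl, yl, zl) {
      g <- global_config(c(xs, ys, zs), c(xo, yo, zo), c(xl, yl, zl))
      L <- norm3(g$rod_end_L - g$rod_end_O)
      wr <- wrench_global(g, s, rod(L, lambda), p, reference_point)
      tibble::tibble(Fx = wr$sphere$force[1], Fy = wr$sphere$force[2],
                     Fz = wr$sphere$force[3], Tx = wr$rod$torque[1],
                     Ty = wr$rod$torque[2], Tz = wr$rod$torque[3],
                     ref_point = reference_point, frame = "global")
    })
  } else if (all(c("rho", "theta", "L") %in% names(configs))) {
    rows <- purrr::pmap(configs[c("rho", "theta", "L")],
                        function(rho, theta, L) {
      cfg <- local_config(rho, theta)
      r <- rod(L, lambda)
      fs <- force_on_sphere(cfg, s, r, p)
      tq <- torque_on_rod(cfg, s, r, p, reference_point)
      tibble::tibble(Fx = fs$force[1], Fy = fs$force[2], Fz = fs$force[3],
                     Tx = tq$torque[1], Ty = tq$torque[2],
                     Tz = tq$torque[3],
                     ref_point = reference_point, frame = "local")
    })
  } else {
    stop("run_wrench_batch(): need columns xs..zl (global) or rho,theta,L (local)",
         call. = FALSE)
  }
  dplyr::bind_cols(configs, dplyr::bind_rows(rows))
}

#' Read a configuration table
#'
#' CSV (comma-separated, `.` decimal, header row, `#` comment lines) or
#' JSON (array of records), selected by file extension.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_config_table <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    tibble::as_tibble(utils::read.csv(path, comment.char = "#",
                                      stringsAsFactors = FALSE))
  }
}

#' Write a result table
#'
#' CSV output carries `#` comment lines with the reduced-unit conventions
#' and any extra metadata; JSON output wraps the rows under `data` with
#' the metadata under `meta`.  Output is byte-deterministic for identical
#' inputs (no timestamps).
#'
#' @param tbl A data frame.
#' @param path Output path.
#' @param format `"csv"` or `"json"` (default from the file extension).
#' @param meta Character vector of extra metadata lines.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(tbl, path,
                               format = c("auto", "csv", "json"),
                               meta = character()) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  units_line <- "units: lengths in sigma, energies in epsilon, lambda in 1/sigma, rho_s in 1/sigma^3"
  if (format == "json") {
    jsonlite::write_json(list(meta = c(units_line, meta),
                              data = as.data.frame(tbl)),
                         path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", c(units_line, meta)), con)
    utils::write.csv(tbl, con, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
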
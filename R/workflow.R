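#' Reproduce the D/Ds estimation-design study
#'
#' Computes the full set of locally D- and Ds-optimal designs for the
#' inhibition models at the built-in nominal estimates: the 4-parameter
#' encompassing designs at `lambda = 0` (non-competitive nominals, `4D_N`),
#' `lambda = 1` (competitive nominals, `4D_C`) and at the encompassing
#' estimates (`4D_E`), the 3-parameter pure-model designs (`3D_N`, `3D_C`)
#' and the Ds designs for `lambda` (`Ds_N`, `Ds_C`), on the requested
#' scale(s).  Every design is certified by its equivalence theorem.
#'
#' @param scale `"log"`, `"standard"` or `"both"`.
#' @param outdir optional directory: one CSV per design plus an
#'   equivalence-check log.
#' @param sub_step standard-scale grid step (the log grid is the fixed
#'   31 x 61 lattice).
#' @return named list of lists of certified designs, by scale.
#' @export
reproduce_table3 <- function(scale = c("both", "log", "standard"),
                             outdir = NULL, sub_step = 0.1) {
  scale <- match.arg(scale)
  scales <- if (scale == "both") c("standard", "log") else scale
  out <- list()
  for (sc in scales) {
    grid <- if (sc == "log") design_grid("log")
            else design_grid("standard", sub_step = sub_step,
                             inh_step = sub_step)
    enc <- model_spec("encompassing", sc)
    designs <- list(
      `4D_N` = optimize_d(grid, enc, encompassing_at("noncompetitive", sc)),
      `4D_C` = optimize_d(grid, enc, encompassing_at("competitive", sc)),
      `4D_E` = optimize_d(grid, enc, nominal_estimates("encompassing", sc)$theta),
      `3D_N` = optimize_d(grid, model_spec("noncompetitive", sc),
                          nominal_estimates("noncompetitive", sc)$theta),
      `3D_C` = optimize_d(grid, model_spec("competitive", sc),
                          nominal_estimates("competitive", sc)$theta),
      `Ds_N` = optimize_ds(grid, enc, encompassing_at("noncompetitive", sc),
                           subset = 4L),
      `Ds_C` = optimize_ds(grid, enc, encompassing_at("competitive", sc),
                           subset = 4L))
    out[[sc]] <- designs
    if (!is.null(outdir)) {
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      log <- character()
      for (nm in names(designs)) {
        write_design_csv(designs[[nm]],
                         file.path(outdir, sprintf("%s_%s.csv", nm, sc)))
        ch <- attr(designs[[nm]], "equivalence")
        log <- c(log, sprintf("%s (%s): max sensitivity %.6f vs bound %d (gap %.2e) -- %s",
                              nm, sc, ch$max_psi, ch$bound, ch$gap,
                              if (ch$pass) "certified" else "NOT certified"))
      }
      writeLines(c("nominal values: built-in initial estimates (see nominal_estimates)",
                   log),
                 file.path(outdir, sprintf("equivalence_%s.log", sc)))
    }
  }
  out
}

# reference model behind each named design (used for efficiency columns)
design_reference <- function(name, sc) {
  switch(name,
         `4D_N` = list(spec = model_spec("encompassing", sc),
                       theta = encompassing_at("noncompetitive", sc), subset = NULL),
         `4D_C` = list(spec = model_spec("encompassing", sc),
                       theta = encompassing_at("competitive", sc), subset = NULL),
         `4D_E` = list(spec = model_spec("encompassing", sc),
                       theta = nominal_estimates("encompassing", sc)$theta, subset = NULL),
         `3D_N` = list(spec = model_spec("noncompetitive", sc),
                       theta = nominal_estimates("noncompetitive", sc)$theta, subset = NULL),
         `3D_C` = list(spec = model_spec("competitive", sc),
                       theta = nominal_estimates("competitive", sc)$theta, subset = NULL),
         `Ds_N` = list(spec = model_spec("encompassing", sc),
                       theta = encompassing_at("noncompetitive", sc), subset = 4L),
         `Ds_C` = list(spec = model_spec("encompassing", sc),
                       theta = encompassing_at("competitive", sc), subset = 4L))
}

#' Cross-table of D and Ds efficiencies
#'
#' Evaluates every design from [reproduce_table3()] under every reference
#' criterion (the model, nominal values and criterion for which each column
#' design is optimal), in percent.  Entries where the row design cannot
#' support the reference model's parameter count are singular and reported
#' as `NA`.
#'
#' @param designs output of [reproduce_table3()] (or a subset of its
#'   scales).
#' @return a list of efficiency matrices, one per (row-scale, column-scale)
#'   combination, rows = designs, columns = reference criteria.
#' @export
reproduce_table4 <- function(designs) {
  scales <- names(designs)
  out <- list()
  for (rsc in scales) for (csc in scales) {
    rows <- designs[[rsc]]; cols <- designs[[csc]]
    M <- matrix(NA_real_, length(rows), length(cols),
                dimnames = list(paste(names(rows), rsc),
                                paste(names(cols), csc)))
    for (j in seq_along(cols)) {
      ref <- design_reference(names(cols)[j], csc)
      for (i in seq_along(rows)) {
        e <- tryCatch({
          if (is.null(ref$subset))
            d_efficiency(rows[[i]], cols[[j]], ref$spec, ref$theta)
          else
            ds_efficiency(rows[[i]], cols[[j]], ref$spec, ref$theta,
                          ref$subset)
        }, error = function(e) NA_real_)
        M[i, j] <- if (isTRUE(attr(e, "singular"))) NA_real_ else as.numeric(e)
      }
    }
    out[[paste(rsc, "vs", csc)]] <- M
  }
  out
}

#' Reproduce the discriminating-design study
#'
#' Computes the T-, compound-T- and Ds-based discriminating designs between
#' the competitive and non-competitive models at the built-in nominals:
#' `A_1` (T-optimal, non-competitive true), `A_2` (CT, `nu = 0.5`), `A_3`
#' (Ds for `lambda` at the encompassing estimates) and `A_4` (T-optimal,
#' competitive true), with both-direction T-efficiencies re-solved per
#' design.
#'
#' @param scale `"log"` (default) or `"standard"`.
#' @param outdir optional output directory for design CSVs.
#' @param sub_step standard-scale grid step for discrimination (default
#'   0.25, refined continuously).
#' @return list with the four designs, the two pure T-results and an
#'   efficiency table (columns: criterion with model 0 = non-competitive
#'   true, criterion with model 1 = competitive true).
#' @export
reproduce_table5 <- function(scale = c("log", "standard"), outdir = NULL,
                             sub_step = 0.25) {
  scale <- match.arg(scale)
  grid <- if (scale == "log") design_grid("log")
          else design_grid("standard", sub_step = sub_step,
                           inh_step = sub_step)
  sN <- model_spec("noncompetitive", scale)
  sC <- model_spec("competitive", scale)
  thN <- nominal_estimates("noncompetitive", scale)$theta
  thC <- nominal_estimates("competitive", scale)$theta
  A1 <- t_optimal(grid, sN, thN, sC)
  A4 <- t_optimal(grid, sC, thC, sN)
  A2 <- ct_optimal(grid, sN, thN, sC, thC, nu = 0.5)
  A3 <- optimize_ds(grid, model_spec("encompassing", scale),
                    nominal_estimates("encompassing", scale)$theta,
                    subset = 4L)
  designs <- list(A1 = A1$design, A2 = A2$design, A3 = A3, A4 = A4$design)
  eff <- data.frame(
    design = names(designs),
    eff_noncomp_true = vapply(designs, t_efficiency, 0, reference = A1),
    eff_comp_true = vapply(designs, t_efficiency, 0, reference = A4))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(designs))
      write_design_csv(designs[[nm]],
                       file.path(outdir, sprintf("%s_%s.csv", nm, scale)))
    utils::write.csv(eff, file.path(outdir, sprintf("t_efficiencies_%s.csv",
                                                    scale)),
                     row.names = FALSE)
  }
  list(designs = designs, t_noncomp = A1, t_comp = A4, ct = A2,
       efficiencies = eff)
}

#' Reproduce the hit-rate simulation study
#'
#' Rounds the discriminating designs to exact designs of sizes `N_values`,
#' optionally adds delta-optimal exact designs for the requested tuning
#' values `r`, and runs the Monte-Carlo hit-rate study for each size
#' (log-scale models, multiplicative error).
#'
#' @param designs named list of approximate designs (default: the printed
#'   log-case discriminating designs recomputed by [reproduce_table5()]).
#' @param N_values exact design sizes (default `6:9`).
#' @param B Monte-Carlo replicates per cell (default 100).
#' @param sigma simulation error SD (default 0.5128, the encompassing
#'   log-fit residual SD).
#' @param r_values delta tuning values to include (default `c(1, 4)`;
#'   `NULL` to skip the delta designs).
#' @param alternative box alternative for the delta designs.
#' @param seed master seed.
#' @param outdir optional directory for the hit-rate CSV.
#' @return data frame: one row per design x N with average hit rates.
#' @export
reproduce_table6 <- function(designs = NULL, N_values = 6:9, B = 100L,
                             sigma = 0.5128, r_values = c(1, 4),
                             alternative = "a", seed = 1L, outdir = NULL) {
  sN <- model_spec("noncompetitive", "log")
  sC <- model_spec("competitive", "log")
  nomN <- nominal_estimates("noncompetitive", "log")
  nomC <- nominal_estimates("competitive", "log")
  if (is.null(designs)) designs <- reproduce_table5("log")$designs
  grid <- design_grid("log")
  out <- list()
  for (N in N_values) {
    ex <- lapply(designs, round_design, N = N)
    for (r in r_values) {
      box0 <- nominal_box(nomC$theta, nomC$se, r, alternative)
      box1 <- nominal_box(nomN$theta, nomN$se, r, alternative)
      ex[[sprintf("delta_r%g%s", r, alternative)]] <-
        delta_optimal(N, grid, sC, sN, box0, box1,
                      seed = (seed + 31L * N + as.integer(100 * r)) %% 2147483647L)
    }
    hr <- hit_rate_study(ex, sN, sC, nomN$theta, nomC$theta, sigma,
                         B = B, seed = (seed + N) %% 2147483647L)
    out[[as.character(N)]] <- hr
  }
  res <- do.call(rbind, out)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(res, file.path(outdir, "hit_rates.csv"),
                     row.names = FALSE)
  }
  res
}
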
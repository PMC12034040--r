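# Mass-action equilibrium of competitive TF-DNA binding:
# Myc-Max heterodimer ("Myc") binds high-GC DNA (DNAH, dissociation constant
# K1) and low-GC DNA (DNAL, K_L); two DNA-bound heterodimers can associate
# into a bivalent heterotetramer on DNAH only (K2), giving
# [Myc]^2 [DNAH]^2 / [(Myc.DNAH)2] = K1^2 K2 = K_H. Smad1 binds both DNA
# classes as a homodimer ([Smad]^2 [DNA] / [Smad2.DNA] = Ktilde). All
# computation is in molar; Ktilde constants are in M^2.

#' Equilibrium model parameters
#'
#' Constants and totals of the competitive Myc/Smad binding model. The
#' heterotetramer constant `K_H = K1^2 * K2` is always derived, never stored.
#' Defaults are the published operating point: `K1` = 145 nM, `K2` = 90 nM,
#' `K_L` = 500 nM, `Ktilde_H` = 1e-14 M^2, `Ktilde_L` = 2.5e-14 M^2,
#' `Smad_tot` = 1 uM, `DNAH_tot` = `DNAL_tot` = 0.5 uM.
#'
#' @param Myc_tot Total Myc-Max heterodimer concentration (M, >= 0).
#' @param K1 Myc.DNAH dissociation constant (M).
#' @param K2 Heterotetramer dissociation constant (M).
#' @param K_L Myc.DNAL dissociation constant (M).
#' @param Ktilde_H,Ktilde_L Smad homodimer-DNA dissociation constants (M^2).
#' @param Smad_tot Total Smad concentration (M, >= 0).
#' @param DNAH_tot,DNAL_tot Total DNA site concentrations (M).
#' @param tetramer Logical; `FALSE` gives the heterodimer-only control model.
#' @return An `equilibrium_parameters` list (with derived `K_H`).
#' @export
equilibrium_parameters <- function(Myc_tot = 1e-6,
                                   K1 = 145e-9, K2 = 90e-9, K_L = 500e-9,
                                   Ktilde_H = 1e-14, Ktilde_L = 2.5e-14,
                                   Smad_tot = 1e-6,
                                   DNAH_tot = 0.5e-6, DNAL_tot = 0.5e-6,
                                   tetramer = TRUE) {
  stopifnot(K1 > 0, K2 > 0, K_L > 0, Ktilde_H > 0, Ktilde_L > 0,
            DNAH_tot > 0, DNAL_tot > 0, Myc_tot >= 0, Smad_tot >= 0)
  structure(
    list(Myc_tot = Myc_tot, K1 = K1, K2 = K2, K_L = K_L,
         Ktilde_H = Ktilde_H, Ktilde_L = Ktilde_L,
         K_H = K1^2 * K2,
         Smad_tot = Smad_tot, DNAH_tot = DNAH_tot, DNAL_tot = DNAL_tot,
         tetramer = isTRUE(tetramer)),
    class = "equilibrium_parameters"
  )
}

#' @export
print.equilibrium_parameters <- function(x, ...) {
  cat(sprintf(paste0(
    "equilibrium_parameters: K1=%.3g M, K2=%.3g M, K_L=%.3g M, ",
    "Ktilde_H=%.3g M^2, Ktilde_L=%.3g M^2\n",
    "totals: Myc=%.3g M, Smad=%.3g M, DNAH=%.3g M, DNAL=%.3g M; tetramer %s\n"),
    x$K1, x$K2, x$K_L, x$Ktilde_H, x$Ktilde_L,
    x$Myc_tot, x$Smad_tot, x$DNAH_tot, x$DNAL_tot,
    if (x$tetramer) "on" else "off"))
  invisible(x)
}

#' Read equilibrium parameters from a YAML file with explicit units
#'
#' Each concentration must carry a unit suffix (`M`, `mM`, `uM`, `nM`, `pM`)
#' and each squared constant the suffix `M^2`, preventing silent M-vs-M^2
#' confusion, e.g. `K1: 145 nM`, `Ktilde_H: 1e-14 M^2`.
#'
#' @param path YAML file path.
#' @return An [equilibrium_parameters()] object.
#' @export
read_equilibrium_parameters <- function(path) {
  raw <- yaml::read_yaml(path)
  conc <- function(x) {
    m <- regmatches(x, regexec("^\\s*([0-9.eE+-]+)\\s*(M|mM|uM|nM|pM)\\s*$",
                               as.character(x)))[[1L]]
    if (length(m) != 3L) stop("cannot parse concentration with units: '", x, "'")
    as.numeric(m[2L]) *
      unname(c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)[m[3L]])
  }
  conc2 <- function(x) {
    m <- regmatches(x, regexec("^\\s*([0-9.eE+-]+)\\s*M\\^?2\\s*$",
                               as.character(x)))[[1L]]
    if (length(m) != 2L) stop("cannot parse M^2 constant with units: '", x, "'")
    as.numeric(m[2L])
  }
  equilibrium_parameters(
    Myc_tot = conc(raw$Myc_tot), K1 = conc(raw$K1), K2 = conc(raw$K2),
    K_L = conc(raw$K_L), Ktilde_H = conc2(raw$Ktilde_H),
    Ktilde_L = conc2(raw$Ktilde_L), Smad_tot = conc(raw$Smad_tot),
    DNAH_tot = conc(raw$DNAH_tot), DNAL_tot = conc(raw$DNAL_tot),
    tetramer = raw$tetramer %||% TRUE
  )
}

#' All species concentrations given the free Myc and Smad concentrations
#'
#' With free Myc `m` and free Smad `s` fixed, DNA conservation is exactly
#' solvable: free DNAL is linear,
#' `[DNAL] = DNAL_tot / (1 + m/K_L + s^2/Ktilde_L)`, and free DNAH is the
#' positive root of the quadratic
#' `2 m^2 h^2 / K_H + h (1 + m/K1 + s^2/Ktilde_H) = DNAH_tot` (the quadratic
#' term present only with the tetramer enabled). Bound species follow from
#' the equilibrium relations.
#'
#' @param m Free Myc concentration (M, >= 0).
#' @param s Free Smad concentration (M, >= 0).
#' @param params [equilibrium_parameters()].
#' @return Named list of concentrations: `DNAH`, `DNAL`, `Myc_DNAH`,
#'   `Myc_DNAH_2`, `Myc_DNAL`, `Smad2_DNAH`, `Smad2_DNAL`.
#' @export
species_from_free <- function(m, s, params) {
  p <- params
  stopifnot(m >= 0, s >= 0)
  l <- p$DNAL_tot / (1 + m / p$K_L + s^2 / p$Ktilde_L)
  b <- 1 + m / p$K1 + s^2 / p$Ktilde_H
  a <- if (p$tetramer) 2 * m^2 / p$K_H else 0
  if (a > 0) {
    disc <- b^2 + 4 * a * p$DNAH_tot
    stopifnot(disc >= 0)
    # positive root, written to avoid cancellation
    h <- 2 * p$DNAH_tot / (b + sqrt(disc))
  } else {
    h <- p$DNAH_tot / b
  }
  mh <- m * h / p$K1
  tet <- if (p$tetramer) mh^2 / p$K2 else 0
  list(DNAH = h, DNAL = l,
       Myc_DNAH = mh, Myc_DNAH_2 = tet, Myc_DNAL = m * l / p$K_L,
       Smad2_DNAH = s^2 * h / p$Ktilde_H, Smad2_DNAL = s^2 * l / p$Ktilde_L)
}

# total Myc / Smad implied by free concentrations (conservation left sides)
.myc_total <- function(m, s, params) {
  sp <- species_from_free(m, s, params)
  m + sp$Myc_DNAH + 2 * sp$Myc_DNAH_2 + sp$Myc_DNAL
}

.smad_total <- function(m, s, params) {
  sp <- species_from_free(m, s, params)
  s + 2 * sp$Smad2_DNAH + 2 * sp$Smad2_DNAL
}

#' Solve the competitive binding equilibrium
#'
#' Reduces the nine-species system to the two free concentrations
#' (free Myc `m`, free Smad `s`) by exact elimination of the DNA species
#' ([species_from_free()]), then solves the Myc and Smad conservation
#' equations by nested Brent root bracketing: both implied totals are
#' strictly increasing in their own free concentration, so the inner solve
#' (free Myc given `s`) and the outer solve (free Smad) each bracket a unique
#' root in `[0, total]`. This is derivative-free, requires no initial guess,
#' and cannot diverge.
#'
#' @param params [equilibrium_parameters()].
#' @return An `equilibrium_state`: list with `free` (named: `Myc`, `Smad`,
#'   `DNAH`, `DNAL`), `bound` (named: `Myc_DNAH`, `Myc_DNAH_2`, `Myc_DNAL`,
#'   `Smad2_DNAH`, `Smad2_DNAL`), `residuals` (relative conservation
#'   residuals for Myc, Smad, DNAH, DNAL), and `params`.
#' @export
solve_equilibrium <- function(params) {
  p <- params
  solve_m <- function(s) {
    if (p$Myc_tot == 0) return(0)
    f <- function(m) .myc_total(m, s, p) - p$Myc_tot
    stats::uniroot(f, c(0, p$Myc_tot), tol = p$Myc_tot * 1e-15,
                   maxiter = 2000L)$root
  }
  if (p$Smad_tot == 0) {
    s <- 0
    m <- solve_m(0)
  } else {
    g <- function(s) .smad_total(solve_m(s), s, p) - p$Smad_tot
    s <- stats::uniroot(g, c(0, p$Smad_tot), tol = p$Smad_tot * 1e-15,
                        maxiter = 2000L)$root
    m <- solve_m(s)
  }
  sp <- species_from_free(m, s, p)
  res <- c(
    Myc = if (p$Myc_tot > 0) (.myc_total(m, s, p) - p$Myc_tot) / p$Myc_tot else 0,
    Smad = if (p$Smad_tot > 0) (.smad_total(m, s, p) - p$Smad_tot) / p$Smad_tot else 0,
    DNAH = (sp$DNAH + sp$Myc_DNAH + 2 * sp$Myc_DNAH_2 + sp$Smad2_DNAH -
              p$DNAH_tot) / p$DNAH_tot,
    DNAL = (sp$DNAL + sp$Myc_DNAL + sp$Smad2_DNAL - p$DNAL_tot) / p$DNAL_tot
  )
  structure(
    list(free = c(Myc = m, Smad = s, DNAH = sp$DNAH, DNAL = sp$DNAL),
         bound = c(Myc_DNAH = sp$Myc_DNAH, Myc_DNAH_2 = sp$Myc_DNAH_2,
                   Myc_DNAL = sp$Myc_DNAL, Smad2_DNAH = sp$Smad2_DNAH,
                   Smad2_DNAL = sp$Smad2_DNAL),
         residuals = res, params = p),
    class = "equilibrium_state"
  )
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat("equilibrium_state (M):\n")
  print(signif(c(x$free, x$bound), 6))
  cat(sprintf("max |relative residual| = %.2e\n", max(abs(x$residuals))))
  invisible(x)
}

#' Sweep the total Myc concentration
#'
#' Solves the equilibrium at every point of a log-spaced total-Myc grid and
#' quantifies the sharpness of the binding transition as the maximum
#' absolute derivative with respect to `log10(Myc_tot)` (central finite
#' differences on the log grid), both for DNAH-bound Smad homodimer and for
#' the Myc heterotetramer.
#'
#' @param params [equilibrium_parameters()] (its `Myc_tot` is ignored).
#' @param grid Increasing vector of total Myc concentrations (M). Default:
#'   200 log-spaced points on `[1e-8, 1e-5]`.
#' @return A `myc_sweep`: list with `myc_tot`, `states` (data frame, one row
#'   per grid point: free and bound species and the residual norm),
#'   `sharpness` (named: `Smad2_DNAH`, `Myc_DNAH_2`, in M per decade), and
#'   `params`.
#' @export
sweep_myc_total <- function(params,
                            grid = 10^seq(-8, -5, length.out = 200L)) {
  stopifnot(all(diff(grid) > 0))
  rows <- lapply(grid, function(g) {
    p <- params
    p$Myc_tot <- g
    st <- solve_equilibrium(p)
    c(myc_tot = g, st$free, st$bound,
      residual_norm = max(abs(st$residuals)))
  })
  states <- as.data.frame(do.call(rbind, rows))
  sharp <- c(
    Smad2_DNAH = .max_log_derivative(grid, states$Smad2_DNAH),
    Myc_DNAH_2 = .max_log_derivative(grid, states$Myc_DNAH_2)
  )
  structure(list(myc_tot = grid, states = states, sharpness = sharp,
                 params = params),
            class = "myc_sweep")
}

# max |dy/dlog10(x)| by central differences; NA for grids of < 3 points
.max_log_derivative <- function(x, y) {
  if (length(x) < 3L) return(NA_real_)
  lx <- log10(x)
  i <- 2:(length(x) - 1L)
  d <- (y[i + 1L] - y[i - 1L]) / (lx[i + 1L] - lx[i - 1L])
  max(abs(d))
}

#' @export
print.myc_sweep <- function(x, ...) {
  cat(sprintf("myc_sweep: %d points on [%.3g, %.3g] M (tetramer %s)\n",
              length(x$myc_tot), min(x$myc_tot), max(x$myc_tot),
              if (x$params$tetramer) "on" else "off"))
  cat(sprintf("sharpness (M/decade): Smad2.DNAH %.3g, (Myc.DNAH)2 %.3g\n",
              x$sharpness["Smad2_DNAH"], x$sharpness["Myc_DNAH_2"]))
  invisible(x)
}

#' Write a sweep as TSV
#'
#' Columns: `myc_tot`, all free and bound species, `residual_norm`.
#'
#' @param sweep A `myc_sweep`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  utils::write.table(sweep$states, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Robustness of the cooperative sharpening to the binding constants
#'
#' Perturbs each dissociation constant multiplicatively (one at a time) and
#' records, for each perturbed parameter set, the sharpness of the
#' DNAH-bound Smad transition with the tetramer enabled and disabled, and
#' whether the cooperative (tetramer) model remains the sharper one.
#'
#' @param params Base [equilibrium_parameters()].
#' @param factors Multiplicative factors applied to each constant (the
#'   identity factor 1 is always included as the first row).
#' @param grid Myc-total grid for the sweeps (default 60 log-spaced points
#'   on `[1e-8, 1e-5]`).
#' @return Data frame with columns `constant`, `factor`, `sharpness_on`,
#'   `sharpness_off`, `cooperative_sharper`.
#' @export
robustness_scan <- function(params, factors = c(0.1, 10),
                            grid = 10^seq(-8, -5, length.out = 60L)) {
  ks <- c("K1", "K2", "K_L", "Ktilde_H", "Ktilde_L")
  cases <- rbind(data.frame(constant = "none", factor = 1,
                            stringsAsFactors = FALSE),
                 expand.grid(constant = ks, factor = factors,
                             stringsAsFactors = FALSE))
  out <- lapply(seq_len(nrow(cases)), function(i) {
    p <- params
    k <- cases$constant[i]
    if (k != "none") p[[k]] <- p[[k]] * cases$factor[i]
    p$K_H <- p$K1^2 * p$K2
    p_on <- p; p_on$tetramer <- TRUE
    p_off <- p; p_off$tetramer <- FALSE
    s_on <- sweep_myc_total(p_on, grid)$sharpness[["Smad2_DNAH"]]
    s_off <- sweep_myc_total(p_off, grid)$sharpness[["Smad2_DNAH"]]
    data.frame(constant = k, factor = cases$factor[i],
               sharpness_on = s_on, sharpness_off = s_off,
               cooperative_sharper = s_on > s_off,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
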
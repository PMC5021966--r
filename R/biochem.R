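# Free and bioavailable 25OHD from the binding-equilibrium model: 25OHD
# partitions between DBP (high-affinity carrier), albumin (low-affinity,
# high-capacity) and a free fraction. Bioavailable = free + albumin-bound
# (the non-DBP fraction).

#' Binding constants for the free-25OHD calculation
#'
#' The standard affinity constants and molecular weights of the
#' free-vitamin-D literature: Ka(DBP) = 7e8 L/mol, Ka(albumin) = 6e5 L/mol,
#' MW(DBP) = 58,000 g/mol, MW(albumin) = 66,430 g/mol,
#' MW(25OHD) = 400.6 g/mol. All configurable.
#'
#' @param ka_dbp,ka_alb affinities, L/mol; DBP must be the high-affinity
#'   carrier (`ka_dbp > ka_alb`).
#' @param mw_dbp,mw_alb,mw_25ohd molecular weights, g/mol.
#' @return list of class `"binding_constants"`.
#' @export
binding_constants <- function(ka_dbp = 7e8, ka_alb = 6e5,
                              mw_dbp = 58000, mw_alb = 66430,
                              mw_25ohd = 400.6) {
  if (any(c(ka_dbp, ka_alb, mw_dbp, mw_alb, mw_25ohd) <= 0)) {
    stop("binding constants must be strictly positive")
  }
  if (ka_dbp <= ka_alb) stop("ka_dbp must exceed ka_alb (DBP is the high-affinity carrier)")
  structure(list(ka_dbp = ka_dbp, ka_alb = ka_alb, mw_dbp = mw_dbp,
                 mw_alb = mw_alb, mw_25ohd = mw_25ohd),
            class = "binding_constants")
}

#' Convert a mass concentration to molarity
#'
#' @param concentration value(s) in the given unit.
#' @param mw molecular weight, g/mol.
#' @param unit one of `"ng/mL"`, `"mg/L"`, `"g/L"`.
#' @return concentration in mol/L.
#' @export
to_molar <- function(concentration, mw, unit = c("ng/mL", "mg/L", "g/L")) {
  unit <- match.arg(unit)
  if (any(concentration < 0, na.rm = TRUE)) stop("concentration must be >= 0")
  if (mw <= 0) stop("molecular weight must be > 0")
  g_per_l <- switch(unit, "ng/mL" = 1e-6, "mg/L" = 1e-3, "g/L" = 1)
  concentration * g_per_l / mw
}

#' Free and bioavailable 25OHD
#'
#' Solves the binding equilibrium for the free 25OHD concentration F given
#' total 25OHD (ng/mL), DBP (mg/L) and albumin (g/L), in molar units:
#'
#' * `method = "linear"` (default, trace-ligand assumption — total far below
#'   the DBP binding capacity):
#'   \deqn{F = T / (1 + K_{alb} [Alb] + K_{dbp} [DBP]).}
#' * `method = "exact"` treats DBP binding as saturable and solves the mass
#'   balance \eqn{T = F (1 + K_{alb}[Alb]) + K_{dbp} F [DBP] / (1 + K_{dbp} F)},
#'   a quadratic in F with a unique non-negative root.
#'
#' Albumin binding is kept in its linear regime in both solvers (albumin is
#' a vast molar excess over 25OHD). Bioavailable = free + albumin-bound.
#'
#' @param total total 25OHD, ng/mL.
#' @param dbp DBP, mg/L.
#' @param albumin albumin, g/L.
#' @param k [binding_constants()].
#' @param method `"linear"` or `"exact"`.
#' @return data.frame with `free_25ohd` (pg/mL), `bioavailable_25ohd`
#'   (ng/mL), `dbp_bound` (ng/mL), `albumin_bound` (ng/mL), `solver`.
#' @export
free_25ohd <- function(total, dbp, albumin, k = binding_constants(),
                       method = c("linear", "exact")) {
  method <- match.arg(method)
  n <- max(length(total), length(dbp), length(albumin))
  total <- rep_len(total, n); dbp <- rep_len(dbp, n)
  albumin <- rep_len(albumin, n)
  if (any(c(total, dbp, albumin) < 0, na.rm = TRUE)) {
    stop("total, dbp and albumin must be >= 0")
  }
  T_m <- to_molar(total, k$mw_25ohd, "ng/mL")
  D_m <- to_molar(dbp, k$mw_dbp, "mg/L")
  A_m <- to_molar(albumin, k$mw_alb, "g/L")
  alb_factor <- 1 + k$ka_alb * A_m
  if (method == "linear") {
    F_m <- T_m / (alb_factor + k$ka_dbp * D_m)
    dbp_bound_m <- k$ka_dbp * F_m * D_m
  } else {
    # ka_dbp*alb_factor * F^2 + (alb_factor + ka_dbp*(D - T)) * F - T = 0
    a <- k$ka_dbp * alb_factor
    b <- alb_factor + k$ka_dbp * (D_m - T_m)
    disc <- b^2 + 4 * a * T_m
    if (any(disc < 0, na.rm = TRUE)) stop("no non-negative root (invalid inputs)")
    F_m <- (-b + sqrt(disc)) / (2 * a)
    F_m <- pmax(F_m, 0)
    dbp_bound_m <- k$ka_dbp * F_m * D_m / (1 + k$ka_dbp * F_m)
  }
  alb_bound_m <- k$ka_alb * A_m * F_m
  data.frame(
    free_25ohd = F_m * k$mw_25ohd * 1e9,                    # pg/mL
    bioavailable_25ohd = (F_m + alb_bound_m) * k$mw_25ohd * 1e6,  # ng/mL
    dbp_bound = dbp_bound_m * k$mw_25ohd * 1e6,
    albumin_bound = alb_bound_m * k$mw_25ohd * 1e6,
    solver = method,
    stringsAsFactors = FALSE
  )
}

#' Append free/bioavailable 25OHD columns to a cohort
#'
#' @param cohort data.frame with `total_25ohd`, `dbp`, `albumin`.
#' @param k [binding_constants()].
#' @param method passed to [free_25ohd()].
#' @return the cohort with `free_25ohd` and `bioavailable_25ohd` added.
#' @export
add_free_d_columns <- function(cohort, k = binding_constants(),
                               method = "linear") {
  stop_if_not_cols(cohort, c("total_25ohd", "dbp", "albumin"))
  ok <- complete.cases(cohort[, c("total_25ohd", "dbp", "albumin")])
  cohort$free_25ohd <- NA_real_
  cohort$bioavailable_25ohd <- NA_real_
  if (any(ok)) {
    res <- free_25ohd(cohort$total_25ohd[ok], cohort$dbp[ok],
                      cohort$albumin[ok], k = k, method = method)
    cohort$free_25ohd[ok] <- res$free_25ohd
    cohort$bioavailable_25ohd[ok] <- res$bioavailable_25ohd
  }
  cohort
}
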
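#' Element-cycle acquisition sums
#'
#' Collapses the five assayed extracellular enzyme activities into the three
#' nutrient-acquisition "cycles": carbon (BG + CBH, cellulose degradation),
#' nitrogen (NAG + LAP, chitin and polypeptide degradation) and phosphorus
#' (AP, phosphoester degradation).
#'
#' @param profiles data frame of per-site enzyme activities with columns
#'   `bg`, `cbh`, `nag`, `lap`, `ap` (nmol per gram dry sediment per hour,
#'   all nonnegative) and optionally `site_id`.
#' @return data frame with columns `site_id`, `c_acq`, `n_acq`, `p_acq`
#'   in the same units as the input activities.
#' @examples
#' acquisition_sums(data.frame(bg = 458.12, cbh = 159.11,
#'                             nag = 114.38, lap = 24.9, ap = 200))
#' @export
acquisition_sums <- function(profiles) {
  profiles <- .check_enzyme_profiles(profiles)
  data.frame(
    site_id = profiles$site_id,
    c_acq = profiles$bg + profiles$cbh,
    n_acq = profiles$nag + profiles$lap,
    p_acq = profiles$ap,
    stringsAsFactors = FALSE
  )
}

.check_enzyme_profiles <- function(profiles) {
  profiles <- as.data.frame(profiles)
  missing <- setdiff(ENZYMES, names(profiles))
  if (length(missing) > 0) {
    .stop_field("enzyme profile is missing column(s): %s",
                paste(missing, collapse = ", "))
  }
  for (e in ENZYMES) {
    v <- profiles[[e]]
    if (!is.numeric(v) || anyNA(v)) {
      .stop_field("enzyme activity '%s' must be numeric with no missing values", e)
    }
    if (any(v < 0)) {
      .stop_field("negative activity in enzyme '%s'", e)
    }
  }
  if (is.null(profiles$site_id)) {
    profiles$site_id <- sprintf("S%02d", seq_len(nrow(profiles)))
  }
  profiles
}

#' Ecoenzymatic stoichiometry vector analysis
#'
#' Quantifies microbial resource limitation from the relative allocation of
#' enzyme activity across C-, N- and P-acquisition. For each site, with
#' acquisition sums C, N, P the analysis places the point
#' \deqn{x = C / (C + P), \quad y = C / (C + N)}
#' and computes the vector length \eqn{\sqrt{x^2 + y^2}} (the C-limitation
#' index: longer vectors mean relatively more effort spent acquiring C) and
#' the vector angle, the angle of (x, y) from the x-axis in degrees. Angles
#' above 45 degrees indicate relative P limitation (P-acquisition effort
#' exceeds N-acquisition effort), below 45 degrees N limitation; the
#' N-limitation index is defined as 90 minus the angle so that larger values
#' mean stronger N limitation. All indices are invariant to rescaling the
#' activities, so they reflect allocation, not total enzyme expression.
#'
#' @param sums data frame with strictly positive columns `c_acq`, `n_acq`,
#'   `p_acq` (see [acquisition_sums()]) and optionally `site_id`.
#' @param balanced_tolerance half-width, in degrees, of the band around the
#'   45-degree boundary classified `BALANCED` rather than `N_LIMITED` /
#'   `P_LIMITED`. Exact ties are measure-zero; the default `1e-9` flags only
#'   numerically exact balance.
#' @return data frame with columns `site_id`, `x`, `y`, `vector_length`,
#'   `vector_angle_deg`, `n_limitation` and factor `limitation_class` with
#'   levels `N_LIMITED`, `P_LIMITED`, `BALANCED`.
#' @examples
#' vector_limitation(data.frame(c_acq = 600, n_acq = 150, p_acq = 300))
#' @export
vector_limitation <- function(sums, balanced_tolerance = 1e-9) {
  sums <- as.data.frame(sums)
  for (col in c("c_acq", "n_acq", "p_acq")) {
    if (is.null(sums[[col]])) .stop_field("missing column '%s'", col)
    if (!is.numeric(sums[[col]]) || anyNA(sums[[col]])) {
      .stop_field("column '%s' must be numeric with no missing values", col)
    }
    if (any(sums[[col]] <= 0)) {
      .stop_field(
        "degenerate profile: '%s' must be strictly positive (vector angle undefined at the origin)",
        col)
    }
  }
  if (!is.numeric(balanced_tolerance) || balanced_tolerance < 0) {
    .stop_field("balanced_tolerance must be a nonnegative number")
  }
  x <- sums$c_acq / (sums$c_acq + sums$p_acq)
  y <- sums$c_acq / (sums$c_acq + sums$n_acq)
  angle <- atan2(y, x) * 180 / pi
  class <- ifelse(abs(angle - 45) <= balanced_tolerance, "BALANCED",
                  ifelse(angle > 45, "P_LIMITED", "N_LIMITED"))
  data.frame(
    site_id = if (is.null(sums$site_id)) sprintf("S%02d", seq_len(nrow(sums))) else sums$site_id,
    x = x,
    y = y,
    vector_length = sqrt(x^2 + y^2),
    vector_angle_deg = angle,
    n_limitation = 90 - angle,
    limitation_class = factor(class, levels = c("N_LIMITED", "P_LIMITED", "BALANCED")),
    stringsAsFactors = FALSE
  )
}

#' Redfield classification of water-column nutrient limitation
#'
#' Converts total nitrogen and total phosphorus concentrations (mg per litre)
#' to a molar N:P ratio and classifies the water column against the Redfield
#' ratio of 16N:1P: ratios above 16 indicate P limitation, ratios at or below
#' 16 N limitation (the boundary is assigned to the N side).
#'
#' @param tn,tp water-column total N and total P in mg per litre; strictly
#'   positive, recycled to a common length.
#' @return data frame with columns `tn`, `tp`, `np_molar_ratio` and factor
#'   `water_limitation` (`N_LIMITED` / `P_LIMITED`).
#' @examples
#' water_limitation(tn = 1.0, tp = 0.04)  # oligotrophic saline lake: P-limited
#' @export
water_limitation <- function(tn, tp) {
  if (!is.numeric(tn) || !is.numeric(tp) || anyNA(tn) || anyNA(tp)) {
    .stop_field("tn and tp must be numeric with no missing values")
  }
  if (any(tn <= 0) || any(tp <= 0)) {
    .stop_field("tn and tp must be strictly positive")
  }
  n <- max(length(tn), length(tp))
  tn <- rep_len(tn, n)
  tp <- rep_len(tp, n)
  ratio <- (tn / .N_MOLAR_MASS) / (tp / .P_MOLAR_MASS)
  data.frame(
    tn = tn, tp = tp, np_molar_ratio = ratio,
    water_limitation = factor(ifelse(ratio > 16, "P_LIMITED", "N_LIMITED"),
                              levels = c("N_LIMITED", "P_LIMITED")),
    stringsAsFactors = FALSE
  )
}

#' Pairwise element-cycle distance between sites
#'
#' Euclidean distance between sites in the space of the five enzyme
#' activities, used as the "difference in the element cycle" when relating
#' enzyme-allocation turnover to community turnover. By default each enzyme
#' column is z-scored across sites first, so that high-activity enzymes (BG
#' is typically an order of magnitude above LAP) do not dominate the
#' distance; raw-scale distance is available with `standardize = FALSE`.
#'
#' @param profiles data frame of per-site enzyme activities (see
#'   [acquisition_sums()] for the required columns); at least two sites.
#' @param standardize z-score each enzyme column before computing distances
#'   (default `TRUE`).
#' @return a [stats::dist] object labelled by `site_id`.
#' @export
element_cycle_distance <- function(profiles, standardize = TRUE) {
  profiles <- .check_enzyme_profiles(profiles)
  if (nrow(profiles) < 2) .stop_field("need at least 2 sites for a distance matrix")
  m <- as.matrix(profiles[, ENZYMES])
  rownames(m) <- profiles$site_id
  if (standardize) {
    sds <- apply(m, 2, sd)
    if (any(sds == 0)) {
      .stop_field(
        "enzyme column(s) %s have zero variance across sites; z-scoring is undefined (use standardize = FALSE)",
        paste(ENZYMES[sds == 0], collapse = ", "))
    }
    m <- scale(m)
  }
  dist(m)
}

#' Pairwise absolute-difference matrix of a per-site scalar
#'
#' Builds the |v_i - v_j| matrix for a per-site quantity (vector length,
#' N-limitation index, a cycle sum, ...) so it can enter a Mantel test
#' against a community dissimilarity matrix.
#'
#' @param values numeric vector, one value per site (at least two).
#' @param labels optional site identifiers used to label the result.
#' @return a [stats::dist] object of absolute differences.
#' @export
scalar_difference_matrix <- function(values, labels = NULL) {
  if (!is.numeric(values) || anyNA(values)) {
    .stop_field("values must be numeric with no missing entries")
  }
  if (length(values) < 2) .stop_field("need at least 2 sites for a difference matrix")
  m <- matrix(values, ncol = 1)
  rownames(m) <- if (is.null(labels)) sprintf("S%02d", seq_along(values)) else labels
  dist(m)  # 1-D Euclidean distance is |v_i - v_j|
}
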
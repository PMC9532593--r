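CHEMISTRY_COLUMNS <- c("site_id", "water_depth", "secchi_depth", "water_temp",
                       "water_salinity", "water_ph", "water_cond", "water_do",
                       "water_tn", "water_tp",
                       "sed_ph", "sed_cond", "sed_tc", "sed_tn", "sed_tp")
ENZYME_COLUMNS <- c("site_id", ENZYMES)

#' Write a synthetic survey to delimited text files
#'
#' Writes `chemistry.csv`, `enzymes.csv` (comma-separated), `bacteria.tsv`,
#' `fungi.tsv` (tab-separated, first column `site_id`) and `truth.json`
#' (the generating config) into `out_dir`.
#'
#' @param survey a `synthetic_survey` from [generate_survey()].
#' @param out_dir output directory, created if absent.
#' @return the output directory, invisibly.
#' @export
write_survey <- function(survey, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(survey$chemistry, file.path(out_dir, "chemistry.csv"), row.names = FALSE)
  write.csv(survey$enzymes, file.path(out_dir, "enzymes.csv"), row.names = FALSE)
  for (grp in c("bacteria", "fungi")) {
    tab <- data.frame(site_id = rownames(survey[[grp]]), survey[[grp]],
                      check.names = FALSE, stringsAsFactors = FALSE)
    write.table(tab, file.path(out_dir, paste0(grp, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(survey$truth)) {
    jsonlite::write_json(unclass(survey$truth), file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out_dir)
}

.read_checked <- function(path, columns, sep) {
  if (!file.exists(path)) .stop_field("input file not found: %s", path)
  tab <- tryCatch(
    read.delim(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) .stop_field("failed to parse %s: %s", path, conditionMessage(e)))
  if (!is.null(columns)) {
    missing <- setdiff(columns, names(tab))
    if (length(missing) > 0) {
      .stop_field("%s is missing required column(s): %s", path,
                  paste(missing, collapse = ", "))
    }
    extra <- setdiff(names(tab), columns)
    if (length(extra) > 0) {
      .stop_field("%s has unknown column(s): %s", path, paste(extra, collapse = ", "))
    }
    tab <- tab[, columns]
  }
  tab
}

#' Read and validate the four survey input tables
#'
#' Reads `chemistry.csv` and `enzymes.csv` (comma-separated, exact schemas)
#' and the `bacteria.tsv` / `fungi.tsv` count tables (tab-separated, first
#' column `site_id`), checks schemas, value validity (nonnegative activities
#' and counts) and site alignment across all four tables, and returns the
#' site-aligned survey list.
#'
#' @param chemistry,enzymes,bacteria,fungi file paths.
#' @return list with `chemistry` and `enzymes` data frames and `bacteria` /
#'   `fungi` count matrices, all in chemistry site order.
#' @export
read_survey_tables <- function(chemistry, enzymes, bacteria, fungi) {
  chem <- .read_checked(chemistry, CHEMISTRY_COLUMNS, ",")
  enz <- .read_checked(enzymes, ENZYME_COLUMNS, ",")
  enz <- .check_enzyme_profiles(enz)[, ENZYME_COLUMNS]
  tables <- list(chemistry = chem, enzymes = enz)
  for (grp in c("bacteria", "fungi")) {
    tab <- .read_checked(if (grp == "bacteria") bacteria else fungi, NULL, "\t")
    if (names(tab)[1] != "site_id") {
      .stop_field("%s table must have 'site_id' as its first column", grp)
    }
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab$site_id
    storage.mode(m) <- "numeric"
    tables[[grp]] <- .check_taxon_table(m)
  }
  sites <- chem$site_id
  if (anyDuplicated(sites)) .stop_field("duplicated site_id in chemistry table")
  for (nm in c("enzymes", "bacteria", "fungi")) {
    other <- if (nm == "enzymes") tables$enzymes$site_id else rownames(tables[[nm]])
    bad <- union(setdiff(sites, other), setdiff(other, sites))
    if (length(bad) > 0) {
      .stop_field("site alignment failure between chemistry and %s: %s",
                  nm, paste(bad, collapse = ", "))
    }
  }
  tables$enzymes <- tables$enzymes[match(sites, tables$enzymes$site_id), ]
  rownames(tables$enzymes) <- NULL
  tables$bacteria <- tables$bacteria[sites, , drop = FALSE]
  tables$fungi <- tables$fungi[sites, , drop = FALSE]
  tables
}

#' Summarise per-site limitation indices
#'
#' Survey-level view of the vector analysis: mean vector length, mean
#' vector angle, mean N-limitation index, limitation-class counts and the
#' mean per-site fraction of total enzyme activity directed at C
#' acquisition, C/(C+N+P), recovered from x and y as 1/(1/x + 1/y - 1).
#'
#' @param limitation per-site table from [vector_limitation()].
#' @return list with `n_sites`, `mean_vector_length`,
#'   `mean_vector_angle_deg`, `mean_n_limitation`, `class_counts` and
#'   `mean_c_fraction`.
#' @export
summarize_limitation <- function(limitation) {
  if (nrow(limitation) == 0) .stop_field("limitation table is empty")
  cf <- 1 / (1 / limitation$x + 1 / limitation$y - 1)
  counts <- table(limitation$limitation_class)
  list(
    n_sites = nrow(limitation),
    mean_vector_length = mean(limitation$vector_length),
    mean_vector_angle_deg = mean(limitation$vector_angle_deg),
    mean_n_limitation = mean(limitation$n_limitation),
    class_counts = as.list(setNames(as.integer(counts), names(counts))),
    mean_c_fraction = mean(cf)
  )
}

.provenance_hash <- function(obj) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(serialize(obj, NULL, version = 2), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full limitation analysis
#'
#' Executes the survey workflow end to end: acquisition sums and the
#' limitation vector analysis per site; Redfield classification of the
#' water column; taxon richness and Bray-Curtis dissimilarity for bacteria
#' and fungi; the element-cycle Euclidean distance and per-index absolute
#' difference matrices; Mantel tests linking each community dissimilarity
#' to each enzyme-side distance; Pearson / OLS / quadratic screens of every
#' enzyme, cycle sum and limitation index against every chemistry covariate
#' (plus richness); and stepwise predictor selection for the C- and
#' N-limitation indices. All randomness (Mantel permutations) derives from
#' `seed`, so a rerun with the same inputs and config is identical.
#'
#' @param survey either the list returned by [read_survey_tables()] /
#'   [generate_survey()], or a named character vector/list of the four file
#'   paths (`chemistry`, `enzymes`, `bacteria`, `fungi`).
#' @param out_dir if non-NULL, tables are written there via
#'   [write_report()].
#' @param permutations Mantel permutations (default 999, minimum 99).
#' @param seed integer seed for the Mantel permutation draws.
#' @param standardize_element_distance z-score enzyme columns before the
#'   element-cycle distance (default `TRUE`).
#' @param balanced_tolerance see [vector_limitation()].
#' @param bray_curtis_mode `"counts"` or `"relative"`, see [bray_curtis()].
#' @param stepwise_criterion `"AIC"` or `"p"`, see [stepwise_select()].
#' @return object of class `enzlim_report`: list of result tables
#'   (`limitation`, `water`, `richness`, `summary`, `mantel`,
#'   `correlations`, `regressions`, `stepwise`) plus a `provenance` block
#'   (config, seed, package version, input hash).
#' @export
run_analyze <- function(survey, out_dir = NULL, permutations = 999, seed = 1,
                        standardize_element_distance = TRUE,
                        balanced_tolerance = 1e-9,
                        bray_curtis_mode = c("counts", "relative"),
                        stepwise_criterion = c("AIC", "p")) {
  bray_curtis_mode <- match.arg(bray_curtis_mode)
  stepwise_criterion <- match.arg(stepwise_criterion)
  if (permutations < 99) .stop_field("permutations must be >= 99")
  if (is.character(survey)) survey <- as.list(survey)
  if (is.list(survey) && all(vapply(survey[c("chemistry", "enzymes", "bacteria", "fungi")],
                                    function(x) is.character(x) && length(x) == 1,
                                    logical(1)))) {
    survey <- read_survey_tables(survey$chemistry, survey$enzymes,
                                 survey$bacteria, survey$fungi)
  }
  chem <- survey$chemistry
  sites <- chem$site_id

  ## per-site stoichiometry
  sums <- acquisition_sums(survey$enzymes)
  vl <- vector_limitation(sums, balanced_tolerance = balanced_tolerance)
  limitation <- cbind(sums, vl[, setdiff(names(vl), "site_id")])
  water <- cbind(site_id = sites,
                 water_limitation(chem$water_tn, chem$water_tp))

  ## community side
  rich <- data.frame(site_id = sites,
                     richness_bacteria = richness(survey$bacteria)[sites],
                     richness_fungi = richness(survey$fungi)[sites],
                     row.names = NULL, stringsAsFactors = FALSE)
  bc <- list(bacteria = bray_curtis(survey$bacteria, mode = bray_curtis_mode),
             fungi = bray_curtis(survey$fungi, mode = bray_curtis_mode))

  ## enzyme-side distance structures
  enzyme_dists <- c(
    list(element_cycle = element_cycle_distance(survey$enzymes,
                                                standardize = standardize_element_distance)),
    lapply(setNames(nm = c("c_acq", "n_acq", "p_acq")),
           function(v) scalar_difference_matrix(sums[[v]], sites)),
    lapply(setNames(nm = c("vector_length", "n_limitation")),
           function(v) scalar_difference_matrix(limitation[[v]], sites))
  )

  ## Mantel layer: each community dissimilarity vs each enzyme-side distance
  set.seed(seed)
  mantel_seeds <- sample.int(.Machine$integer.max - 1L,
                             length(bc) * length(enzyme_dists))
  mantel_rows <- list()
  k <- 0
  for (grp in names(bc)) {
    for (dn in names(enzyme_dists)) {
      k <- k + 1
      mt <- mantel_test(bc[[grp]], enzyme_dists[[dn]],
                        n_perm = permutations, seed = mantel_seeds[k])
      mantel_rows[[k]] <- data.frame(
        pair = paste(grp, dn, sep = "_vs_"), matrix_a = grp, matrix_b = dn,
        r = mt$r, p_value = mt$p_value, n_perm = mt$n_perm,
        seed = mantel_seeds[k], stringsAsFactors = FALSE)
    }
  }
  mantel_tab <- do.call(rbind, mantel_rows)

  ## univariate screens: responses x (chemistry covariates + richness)
  responses <- cbind(limitation[, c("vector_length", "vector_angle_deg",
                                    "n_limitation", "c_acq", "n_acq", "p_acq")],
                     survey$enzymes[, ENZYMES])
  predictors <- cbind(chem[, setdiff(CHEMISTRY_COLUMNS, "site_id")],
                      rich[, c("richness_bacteria", "richness_fungi")])
  cor_rows <- list(); reg_rows <- list()
  for (rn in names(responses)) {
    for (pn in names(predictors)) {
      y <- responses[[rn]]; x <- predictors[[pn]]
      if (sd(x) == 0 || sd(y) == 0) next
      pc <- pearson_cor(x, y)
      cor_rows[[length(cor_rows) + 1]] <- data.frame(
        response = rn, predictor = pn, r = pc$r, p_value = pc$p_value, n = pc$n,
        stringsAsFactors = FALSE)
      ## one row per model: the linear slope, and the quadratic curvature term
      lin <- ols_fit(y, setNames(data.frame(x), pn))
      qd <- quadratic_fit(y, x)
      lin_cf <- lin$coefficients[lin$coefficients$term == pn, ]
      qd_cf <- qd$fit$coefficients[qd$fit$coefficients$term == "x_sq", ]
      reg_rows[[length(reg_rows) + 1]] <- data.frame(
        response = rep(rn, 2),
        terms = c(pn, paste0(pn, "+", pn, "^2")),
        coef = c(lin_cf$estimate, qd_cf$estimate),
        se = c(lin_cf$se, qd_cf$se),
        t = c(lin_cf$t, qd_cf$t),
        p = c(lin_cf$p_value, qd_cf$p_value),
        r2 = c(lin$r_squared, qd$fit$r_squared),
        adj_r2 = c(lin$adj_r_squared, qd$fit$adj_r_squared),
        shape = c(NA_character_, qd$shape), stringsAsFactors = FALSE)
    }
  }
  correlations <- do.call(rbind, cor_rows)
  regressions <- do.call(rbind, reg_rows)

  ## stepwise screens for the two headline limitation indices
  chem_candidates <- chem[, setdiff(CHEMISTRY_COLUMNS, "site_id")]
  chem_candidates <- chem_candidates[, vapply(chem_candidates, sd, numeric(1)) > 0,
                                     drop = FALSE]
  step_rows <- lapply(c("vector_length", "n_limitation"), function(rn) {
    sw <- stepwise_select(limitation[[rn]], chem_candidates,
                          criterion = stepwise_criterion)
    data.frame(response = rn,
               selected = paste(sw$selected, collapse = ","),
               criterion = if (stepwise_criterion == "AIC") AIC(sw$fit$model) else NA_real_,
               final_r2 = sw$fit$r_squared, stringsAsFactors = FALSE)
  })
  stepwise <- do.call(rbind, step_rows)

  provenance <- list(
    package = "enzlim",
    version = as.character(utils::packageVersion("enzlim")),
    seed = seed,
    config = list(permutations = permutations,
                  standardize_element_distance = standardize_element_distance,
                  balanced_tolerance = balanced_tolerance,
                  bray_curtis_mode = bray_curtis_mode,
                  stepwise_criterion = stepwise_criterion),
    input_hash = .provenance_hash(list(chem, survey$enzymes, survey$bacteria,
                                       survey$fungi, permutations, seed,
                                       standardize_element_distance,
                                       balanced_tolerance, bray_curtis_mode,
                                       stepwise_criterion))
  )

  report <- structure(list(
    limitation = limitation, water = water, richness = rich,
    summary = summarize_limitation(vl), mantel = mantel_tab,
    correlations = correlations, regressions = regressions,
    stepwise = stepwise, provenance = provenance
  ), class = "enzlim_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write an analysis report to disk
#'
#' Writes `limitation.tsv`, `water.tsv`, `richness.tsv`, `mantel.tsv`,
#' `correlations.tsv`, `regressions.tsv`, `stepwise.tsv`, `summary.json`
#' and `run.log` into `out_dir`. Output is deterministic: identical inputs,
#' config and seed give byte-identical files.
#'
#' @param report an `enzlim_report` from [run_analyze()].
#' @param out_dir output directory, created if absent.
#' @return the output directory, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(tab, name) {
    write.table(tab, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  tsv(report$limitation, "limitation.tsv")
  tsv(report$water, "water.tsv")
  tsv(report$richness, "richness.tsv")
  tsv(report$mantel, "mantel.tsv")
  tsv(report$correlations, "correlations.tsv")
  tsv(report$regressions, "regressions.tsv")
  tsv(report$stepwise, "stepwise.tsv")
  jsonlite::write_json(c(report$summary, list(provenance = report$provenance)),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_lines <- c(
    sprintf("enzlim %s analysis", report$provenance$version),
    sprintf("input hash: %s", report$provenance$input_hash),
    sprintf("sites: %d", report$summary$n_sites),
    sprintf("seed: %d; mantel permutations: %d", report$provenance$seed,
            report$provenance$config$permutations),
    sprintf("mantel tests: %d; screened pairs: %d", nrow(report$mantel),
            nrow(report$correlations)))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' @export
print.enzlim_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Limitation analysis of %d sites\n", s$n_sites))
  cat(sprintf("  mean vector length (C limitation) %.3f; mean angle %.2f deg; mean N-limitation %.2f\n",
              s$mean_vector_length, s$mean_vector_angle_deg, s$mean_n_limitation))
  cat(sprintf("  class counts: %s\n",
              paste(sprintf("%s=%d", names(s$class_counts), unlist(s$class_counts)),
                    collapse = ", ")))
  cat(sprintf("  mean C fraction of total EEA: %.3f\n", s$mean_c_fraction))
  cat(sprintf("  Mantel tests: %d (min p = %.4g)\n", nrow(x$mantel), min(x$mantel$p_value)))
  invisible(x)
}
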
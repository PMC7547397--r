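battery_columns <- function() {
  c(paste0("pcl5_q", 1:20), paste0("dass_q", 1:21),
    paste0("res_q", 1:9), paste0("mhc_q", 1:14))
}

# md5 of the serialized object; a stable provenance fingerprint
config_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(serialize(x, NULL, version = 2), tmp)
  unname(tools::md5sum(tmp))
}

#' Read and screen a respondent cohort
#'
#' Reads a cohort CSV (or screens an in-memory data frame) and applies the
#' exclusion rules of the evaluation design, in order: proxy use
#' (\code{is_proxy}), repeated measurements (\code{is_repeat}), incomplete
#' records (missing MIRROR items/context, or a partially completed reference
#' battery), externally flagged unusual answering patterns
#' (\code{flagged_invalid}), and records violating the response contract
#' (range or vocabulary violations). Each rejected row is counted under the
#' first matching reason and logged; nothing is silently dropped.
#'
#' @param path CSV path (UTF-8, comma-separated, header mandatory, booleans
#'   true/false) or a data frame.
#' @param drop_proxy,drop_repeats,drop_flagged Apply the respective exclusion
#'   (all default \code{TRUE}).
#' @return Object of class \code{cohort_file}: \code{data} (accepted rows),
#'   \code{n_input}, \code{n_accepted}, \code{rejections} (named counts for
#'   proxy / repeat / incomplete / flagged / invalid), \code{log} (one row per
#'   rejection).
#' @export
read_cohort <- function(path, drop_proxy = TRUE, drop_repeats = TRUE,
                        drop_flagged = TRUE) {
  df <- if (is.data.frame(path)) path
        else utils::read.csv(path, stringsAsFactors = FALSE)
  need <- mirror_columns()
  missing_cols <- setdiff(setdiff(need, c("respondent_id", "is_repeat")),
                          names(df))
  if (length(missing_cols))
    stop("missing mandatory columns: ", paste(missing_cols, collapse = ", "))
  if (is.null(df$respondent_id))
    df$respondent_id <- if (nrow(df)) sprintf("R%05d", seq_len(nrow(df))) else character(0)
  for (flag in c("is_repeat", "is_proxy", "flagged_invalid", "recurring")) {
    if (is.null(df[[flag]])) df[[flag]] <- FALSE
    if (is.character(df[[flag]])) df[[flag]] <- as.logical(toupper(df[[flag]]))
    df[[flag]][is.na(df[[flag]])] <- FALSE
  }
  n <- nrow(df)
  bat <- intersect(battery_columns(), names(df))
  reason <- rep(NA_character_, n)
  detail <- rep("", n)
  for (i in seq_len(n)) {
    row <- df[i, ]
    if (drop_proxy && isTRUE(row$is_proxy)) {
      reason[i] <- "proxy"
    } else if (drop_repeats && isTRUE(row$is_repeat)) {
      reason[i] <- "repeat"
    } else {
      viol <- response_violations(row)
      incomplete <- grepl("^incomplete", viol)
      bat_vals <- if (length(bat)) unlist(row[bat]) else numeric(0)
      bat_partial <- length(bat_vals) > 0 && anyNA(bat_vals) && !all(is.na(bat_vals))
      if (any(incomplete) || bat_partial) {
        reason[i] <- "incomplete"
        detail[i] <- paste(c(viol[incomplete],
                             if (bat_partial) "partial reference battery"),
                           collapse = "; ")
      } else if (drop_flagged && isTRUE(row$flagged_invalid)) {
        reason[i] <- "flagged"
      } else if (length(viol)) {
        reason[i] <- "invalid"
        detail[i] <- paste(viol, collapse = "; ")
      }
    }
  }
  rejected <- !is.na(reason)
  counts <- vapply(c("proxy", "repeat", "incomplete", "flagged", "invalid"),
                   function(r) sum(reason == r, na.rm = TRUE), numeric(1))
  log <- data.frame(row = which(rejected),
                    respondent_id = df$respondent_id[rejected],
                    reason = reason[rejected], detail = detail[rejected],
                    stringsAsFactors = FALSE)
  structure(list(data = df[!rejected, , drop = FALSE],
                 n_input = n, n_accepted = sum(!rejected),
                 rejections = counts, log = log),
            class = "cohort_file")
}

#' @rdname read_cohort
#' @param data Data frame of accepted rows.
#' @export
write_cohort <- function(data, path) {
  out <- data
  for (col in names(out))
    if (is.logical(out[[col]])) out[[col]] <- tolower(as.character(out[[col]]))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @export
print.cohort_file <- function(x, ...) {
  cat(sprintf("Cohort: %d rows read, %d accepted (%.2f%%)\n",
              x$n_input, x$n_accepted,
              if (x$n_input) 100 * x$n_accepted / x$n_input else 100))
  rej <- x$rejections[x$rejections > 0]
  if (length(rej))
    cat("  rejected:", paste(sprintf("%s %d", names(rej), rej),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Completion-rate summary for usage statistics
#'
#' @param started,finished Non-negative counts of respondents who started and
#'   finished the instrument.
#' @return List with the counts and \code{completion_pct} (exact percentage).
#' @export
usage_summary <- function(started, finished) {
  stopifnot(started >= finished, finished >= 0)
  list(started = started, finished = finished,
       completion_pct = 100 * finished / started)
}

has_complete_battery <- function(df) {
  bat <- battery_columns()
  if (!all(bat %in% names(df))) return(rep(FALSE, nrow(df)))
  stats::complete.cases(df[bat])
}

mirror_efa_model2 <- function() {
  list(complaints = paste0("mirror_q", 1:4),
       resources = c("mirror_functioning", paste0("mirror_q", 6:8)))
}

mirror_efa_model3 <- function() {
  list(intrusion = c("mirror_q1", "mirror_q2"),
       avoidance = c("mirror_q3", "mirror_q4"),
       resources = c("mirror_functioning", paste0("mirror_q", 6:8)))
}

#' Run the full evaluation pipeline
#'
#' Triages every accepted respondent and, when reference batteries are
#' present, runs the complete psychometric evaluation: reliability of the
#' PTSD and resilience scales, polychoric correlations of the 8 items,
#' eigenvalues, 2- and 3-factor geomin EFA, 2- vs 3-factor CFA comparison,
#' the validity correlation matrix, per-outcome reference-measure summaries,
#' the ANOVA panel (classic and Welch with Games-Howell post hocs), and the
#' outcome-by-sample chi-square (battery completers vs MIRROR-only).
#'
#' @param cohort A \code{cohort_file}, data frame, or CSV path.
#' @param cfg Triage configuration.
#' @param psychometrics Run the evaluation sections (default \code{TRUE};
#'   triage always runs).
#' @return Object of class \code{run_report}: a nested list that serializes
#'   to JSON via \code{\link{write_run_report}}.
#' @export
run_pipeline <- function(cohort, cfg = default_triage_config(),
                         psychometrics = TRUE) {
  cf <- if (inherits(cohort, "cohort_file")) cohort else read_cohort(cohort)
  d <- triage_cohort(cf$data, cfg)
  report <- list(
    provenance = list(package = "mirrorscreen",
                      version = as.character(utils::packageVersion("mirrorscreen")),
                      config_hash = config_hash(cfg)),
    sample = list(n_input = cf$n_input, n_accepted = cf$n_accepted,
                  retained_pct = if (cf$n_input)
                    100 * cf$n_accepted / cf$n_input else 100,
                  rejections = as.list(cf$rejections)),
    triage = list(colors = as.list(table(d$color)),
                  phases = as.list(table(d$phase)),
                  levels = list(ptsd = as.list(table(d$ptsd_level)),
                                functioning = as.list(table(d$functioning_level)),
                                resilience = as.list(table(d$resilience_level)))))
  validation <- has_complete_battery(d)
  report$sample$n_validation <- sum(validation)
  report$sample$validation_share_pct <-
    if (cf$n_accepted) 100 * sum(validation) / cf$n_accepted else 0
  if (!psychometrics || nrow(d) < 50) {
    report$evaluation <- list(status = if (!psychometrics) "not requested"
                              else "cohort too small")
    return(structure(report, class = "run_report"))
  }
  items8 <- c(paste0("mirror_q", 1:4), "mirror_functioning",
              paste0("mirror_q", 6:8))
  R <- correlation_matrix(d, items8, method = "polychoric")
  efa2 <- efa_geomin(R, 2)
  efa3 <- efa_geomin(R, 3)
  cfa2 <- cfa_fit(mirror_efa_model2(), R)
  cfa3 <- cfa_fit(mirror_efa_model3(), R)
  cmp <- cfa_compare(cfa2, cfa3)
  rel_ptsd <- reliability_report(d[paste0("mirror_q", 1:4)])
  rel_res <- reliability_report(d[paste0("mirror_q", 6:8)])
  report$evaluation <- list(
    status = "complete",
    reliability = list(
      ptsd = list(alpha = rel_ptsd$alpha,
                  interitem = as.list(rel_ptsd$interitem),
                  item_total = as.list(rel_ptsd$item_total)),
      resilience = list(alpha = rel_res$alpha,
                        interitem = as.list(rel_res$interitem),
                        item_total = as.list(rel_res$item_total))),
    eigenvalues = efa2$eigenvalues,
    kaiser_factors = kaiser_criterion(efa2),
    efa = list(two_factor = list(loadings = efa2$loadings,
                                 factor_correlations = efa2$factor_correlations,
                                 fit = unclass(efa2$fit)),
               three_factor = list(loadings = efa3$loadings,
                                   factor_correlations = efa3$factor_correlations,
                                   fit = unclass(efa3$fit))),
    cfa = list(two_factor = unclass(cfa2$fit),
               three_factor = unclass(cfa3$fit),
               comparison = cmp))
  if (any(validation)) {
    v <- score_reference_battery(d[validation, , drop = FALSE])
    vr <- tryCatch(validity_report(v), error = function(e) NULL)
    measures <- c(pcl5_total = "PCL-5", dass_depression = "depression",
                  dass_anxiety = "anxiety", dass_stress = "stress",
                  res_total = "RES", mhc_total = "MHC-SF")
    by_color <- lapply(names(measures), function(col) {
      ag <- lapply(split(v[[col]], v$color), function(x)
        list(mean = mean(x), sd = stats::sd(x), n = length(x)))
      ag
    })
    names(by_color) <- measures
    usable <- table(v$color) >= 2
    anovas <- if (sum(usable) >= 2) lapply(names(measures), function(col) {
      keep <- v$color %in% names(usable)[usable]
      list(classic = unclass(oneway_anova(v[[col]][keep],
                                          droplevels(v$color[keep]),
                                          variant = "classic"))[
             c("F", "df_between", "df_within", "p_value", "eta_squared")],
           welch = unclass(oneway_anova(v[[col]][keep],
                                        droplevels(v$color[keep]),
                                        variant = "welch"))[
             c("F", "df_between", "df_within", "p_value", "eta_squared")],
           games_howell = games_howell(v[[col]][keep],
                                       droplevels(v$color[keep])))
    }) else NULL
    if (!is.null(anovas)) names(anovas) <- measures
    report$validation <- list(
      n = sum(validation),
      validity = if (!is.null(vr)) list(r = vr$r, p_value = vr$p_value,
                                        n = vr$n) else NULL,
      outcome_summaries = by_color,
      anova = anovas,
      pcl5_diagnosis_rate_pct = 100 * mean(v$pcl5_diagnosis))
    if (any(!validation) && sum(validation) > 0) {
      tab <- table(d$color, ifelse(validation, "validation", "mirror_only"))
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
        cs <- chi_square_independence(tab)
        report$validation$outcome_sample_chi_square <-
          list(chi_square = cs$chi_square, df = cs$df, p_value = cs$p_value)
      }
    }
  }
  structure(report, class = "run_report")
}

#' Serialize a run report to JSON
#'
#' Every number shown by the report's print method is present in this JSON
#' twin.
#'
#' @param report A \code{run_report}.
#' @param path Output path.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("MIRROR run report (config", x$provenance$config_hash, ")\n")
  cat(sprintf("Sample: %d read, %d accepted (%.2f%%), %d with full battery (%.2f%%)\n",
              x$sample$n_input, x$sample$n_accepted, x$sample$retained_pct,
              x$sample$n_validation, x$sample$validation_share_pct))
  cat("Triage:", paste(sprintf("%s %d", names(x$triage$colors),
                               unlist(x$triage$colors)), collapse = ", "), "\n")
  if (!is.null(x$evaluation) && identical(x$evaluation$status, "complete")) {
    cat(sprintf("Reliability: PTSD alpha %.2f, resilience alpha %.2f\n",
                x$evaluation$reliability$ptsd$alpha,
                x$evaluation$reliability$resilience$alpha))
    cat(sprintf("Kaiser criterion: %d factors; eigenvalues %s\n",
                x$evaluation$kaiser_factors,
                paste(round(x$evaluation$eigenvalues, 3), collapse = " ")))
    cat(sprintf("CFA: 2-factor CFI %.3f vs 3-factor CFI %.3f (delta %.4f, prefer %s)\n",
                x$evaluation$cfa$two_factor$CFI,
                x$evaluation$cfa$three_factor$CFI,
                x$evaluation$cfa$comparison$delta_cfi,
                x$evaluation$cfa$comparison$prefer))
  } else if (!is.null(x$evaluation)) {
    cat("Evaluation:", x$evaluation$status, "\n")
  }
  invisible(x)
}
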
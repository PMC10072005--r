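#' Assemble the per-subject feature table
#'
#' Collects the eight threshold-AUC features of every subject into a
#' \linkS4class{SummarizedExperiment} (features in rows, subjects in
#' columns) with the subject metadata as \code{colData}, plus the
#' per-threshold metric curves as a long-format companion.
#'
#' @param profiles list of \linkS4class{MetricProfile}, one per subject.
#' @param meta data.frame of subject metadata (subject_id, group, age,
#'   gender, FMA, ...) in the same order.
#' @return A SummarizedExperiment with assay \code{"auc"}; the long
#'   per-threshold table is in \code{metadata(x)$perThreshold}.
#' @export
featureTable <- function(profiles, meta) {
  stopifnot2(length(profiles) == nrow(meta),
             "one metadata row per profile required")
  ids <- vapply(profiles, function(p) p@subjectId, character(1))
  stopifnot2(all(ids == meta$subject_id),
             "profile subject ids must match meta$subject_id")
  auc <- vapply(profiles, metricAUCs, numeric(8))
  colnames(auc) <- ids
  long <- do.call(rbind, lapply(profiles, function(p) {
    cv <- metricCurves(p)
    data.frame(subject_id = p@subjectId,
               threshold = rep(p@thresholds, ncol(cv)),
               metric = rep(colnames(cv), each = nrow(cv)),
               value = as.vector(cv), stringsAsFactors = FALSE)
  }))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(auc = auc),
    colData = S4Vectors::DataFrame(meta, row.names = ids),
    metadata = list(perThreshold = long))
}

# feature table (SummarizedExperiment or data.frame) -> analysis data.frame
.featureFrame <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    df <- cbind(as.data.frame(t(SummarizedExperiment::assay(x, "auc"))),
                as.data.frame(SummarizedExperiment::colData(x)))
  } else {
    df <- as.data.frame(x)
  }
  stopifnot2(all(c("group", "age", "gender") %in% names(df)),
             "feature table needs group, age and gender columns")
  df$group <- factor(df$group, levels = intersect(
    c("Healthy", "Mild", "MtS"), unique(as.character(df$group))))
  df$gender <- factor(df$gender)
  df
}

.ancovaFit <- function(df, feature) {
  stopifnot2(feature %in% names(df), paste("unknown feature:", feature))
  counts <- table(df$group)
  stopifnot2(length(counts) >= 2 && all(counts >= 2),
             "need at least 2 groups with at least 2 subjects each")
  form <- stats::as.formula(
    paste0("`", feature, "` ~ group + age + gender"))
  fit <- lm(form, data = df)
  al <- is.na(coef(fit))
  if (any(al))
    stop("rank-deficient model: collinear column(s) ",
         paste(names(al)[al], collapse = ", "), call. = FALSE)
  fit
}

#' Covariate-adjusted group effect (ANCOVA)
#'
#' Fits \code{feature ~ group + age + gender} and tests the group term by
#' a partial F-test against the full-model residual.
#'
#' @param table feature table (SummarizedExperiment from
#'   \code{\link{featureTable}} or a data.frame with the feature, group,
#'   age and gender columns).
#' @param feature feature column name, e.g. \code{"C_AUC"}.
#' @return List with F, df1, df2, p and the fitted model.
#' @export
ancovaGroupEffect <- function(table, feature) {
  df <- .featureFrame(table)
  fit <- .ancovaFit(df, feature)
  red <- update(fit, . ~ . - group)
  an <- anova(red, fit)
  list(F = an$F[2], df1 = an$Df[2], df2 = an$Res.Df[2],
       p = an$`Pr(>F)`[2], model = fit)
}

#' Pairwise covariate-adjusted contrasts (LSD convention)
#'
#' Pairwise t-tests of the covariate-adjusted group means using the
#' pooled full-model error, with no further p adjustment (Fisher's LSD:
#' the gating is the omnibus ANCOVA, which the caller decides on).
#'
#' @inheritParams ancovaGroupEffect
#' @return data.frame with contrast, estimate, t, df and p for each group
#'   pair.
#' @export
posthocPairwiseLSD <- function(table, feature) {
  df <- .featureFrame(table)
  fit <- .ancovaFit(df, feature)
  emm <- emmeans::emmeans(fit, "group")
  ctr <- summary(emmeans::contrast(emm, method = "pairwise",
                                   adjust = "none"))
  data.frame(contrast = as.character(ctr$contrast),
             estimate = ctr$estimate, t = ctr$t.ratio, df = ctr$df,
             p = ctr$p.value, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH adjusted p-values (monotone in the input ranks), as used
#' across the 41 per-threshold tests of one metric.
#'
#' @param pvalues vector of p-values in [0, 1].
#' @return Adjusted p-values of the same length.
#' @examples
#' fdrBH(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
fdrBH <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(pvalues, method = "BH")
}

#' Partial correlation with linear covariate control
#'
#' Pearson correlation of the residuals of \code{x} and \code{y} after
#' regressing each on the covariates; the p-value uses a t reference
#' distribution with \code{n - 2 - k} degrees of freedom (k covariates).
#' With no covariates this reduces exactly to the plain Pearson
#' correlation test.
#'
#' @param x,y numeric vectors.
#' @param covariates optional numeric matrix / data.frame of covariates
#'   (factors allowed in a data.frame).
#' @return List with r, df, t and p; r is \code{NA} (with a warning) if
#'   either residual is constant.
#' @export
partialCorrelation <- function(x, y, covariates = NULL) {
  stopifnot2(length(x) == length(y), "x and y must have equal length")
  n <- length(x)
  if (is.null(covariates) || NCOL(covariates) == 0) {
    k <- 0
    rx <- x - mean(x)
    ry <- y - mean(y)
  } else {
    cv <- as.data.frame(covariates)
    mm <- stats::model.matrix(~ ., data = cv)
    k <- ncol(mm) - 1
    stopifnot2(n > k + 2, "need n > number of covariates + 2")
    rx <- stats::lm.fit(mm, x)$residuals
    ry <- stats::lm.fit(mm, y)$residuals
  }
  if (sd(rx) == 0 || sd(ry) == 0) {
    warning("constant residuals: partial correlation undefined")
    return(list(r = NA_real_, df = n - 2 - k, t = NA_real_, p = NA_real_))
  }
  r <- cor(rx, ry)
  df <- n - 2 - k
  t <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, df = df, t = t, p = 2 * pt(-abs(t), df))
}

#' Full group-statistics report
#'
#' Per AUC feature: omnibus ANCOVA (group effect, age and gender as
#' covariates) and LSD posthoc contrasts; per threshold and metric:
#' the same covariate-adjusted omnibus test with BH-FDR across the
#' thresholds of each metric; and partial correlations of every patient
#' AUC feature with FMA (age and gender controlled).
#'
#' @param table feature table from \code{\link{featureTable}}.
#' @param perThreshold optional long per-threshold table (subject_id,
#'   threshold, metric, value); taken from the table's metadata when
#'   available.
#' @return List of class \code{"motornetGroupReport"} with elements
#'   \code{aucTests}, \code{posthoc}, \code{perThreshold} and
#'   \code{fmaCorrelations}.
#' @export
runGroupAnalysis <- function(table, perThreshold = NULL) {
  df <- .featureFrame(table)
  feats <- c("C_AUC", "L_AUC", "GE_AUC", "LE_AUC", "T_AUC",
             "gamma_AUC", "lambda_AUC", "delta_AUC")
  feats <- intersect(feats, names(df))
  aucTests <- do.call(rbind, lapply(feats, function(f) {
    a <- ancovaGroupEffect(df, f)
    data.frame(feature = f, F = a$F, df1 = a$df1, df2 = a$df2, p = a$p,
               stringsAsFactors = FALSE)
  }))
  aucTests$significant <- aucTests$p < 0.05
  posthoc <- do.call(rbind, lapply(feats, function(f) {
    ph <- posthocPairwiseLSD(df, f)
    ph$feature <- f
    ph$gated <- aucTests$significant[aucTests$feature == f]
    ph
  }))
  if (is.null(perThreshold) && is(table, "SummarizedExperiment"))
    perThreshold <- S4Vectors::metadata(table)$perThreshold
  thrTests <- NULL
  if (!is.null(perThreshold)) {
    thrTests <- do.call(rbind, lapply(split(perThreshold,
                                            perThreshold$metric),
                                      function(mt) {
      out <- do.call(rbind, lapply(split(mt, mt$threshold), function(tt) {
        sub <- merge(tt[, c("subject_id", "value")],
                     df[, c("subject_id", "group", "age", "gender")],
                     by = "subject_id")
        a <- ancovaGroupEffect(sub, "value")
        data.frame(metric = mt$metric[1], threshold = tt$threshold[1],
                   F = a$F, p = a$p, stringsAsFactors = FALSE)
      }))
      out <- out[order(out$threshold), ]
      out$p_fdr <- fdrBH(out$p) # family: the thresholds of one metric
      out
    }))
    rownames(thrTests) <- NULL
  }
  patients <- df[!is.na(df$FMA), , drop = FALSE]
  fmaCor <- NULL
  if (nrow(patients) > 5) {
    fmaCor <- do.call(rbind, lapply(feats, function(f) {
      pc <- partialCorrelation(patients[[f]], patients$FMA,
                               patients[, c("age", "gender")])
      data.frame(feature = f, r = pc$r, df = pc$df, p = pc$p,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(aucTests = aucTests, posthoc = posthoc,
                 perThreshold = thrTests, fmaCorrelations = fmaCor),
            class = "motornetGroupReport")
}

#' Write a group report as JSON (plus CSV side tables)
#'
#' @param report a \code{"motornetGroupReport"}.
#' @param path output JSON path; CSVs are written next to it.
#' @return Invisibly, the JSON path.
#' @export
writeGroupReport <- function(report, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  payload <- list(schema = "motornet-group-report/1",
                  aucTests = report$aucTests, posthoc = report$posthoc,
                  perThreshold = report$perThreshold,
                  fmaCorrelations = report$fmaCorrelations)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  for (nm in c("aucTests", "posthoc", "perThreshold", "fmaCorrelations"))
    if (!is.null(report[[nm]]))
      write.csv(report[[nm]],
                file.path(dirname(path), paste0(nm, ".csv")),
                row.names = FALSE)
  invisible(path)
}
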
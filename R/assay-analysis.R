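# Nitrite time series -> AOI% inhibition statistics, group comparisons and
# compound x strain clustering.

#' Convert Griess absorbances to nitrite concentrations
#'
#' Fits a linear standard curve (absorbance ~ concentration) to at least
#' three standards and maps sample absorbances to nitrite concentrations by
#' inversion, with extrapolation allowed. Reader plumbing for the
#' colorimetric (540 nm) nitrite assay.
#'
#' @param absorbance numeric sample absorbances (AU).
#' @param standards data.frame with columns \code{concentration_uM} and
#'   \code{absorbance} (>= 3 rows).
#' @return numeric nitrite concentrations (uM), with attributes
#'   \code{r_squared}, \code{slope} and \code{intercept} of the fitted curve.
#' @examples
#' std <- data.frame(concentration_uM = c(0, 25, 50, 100),
#'                   absorbance = c(0, 0.25, 0.5, 1))
#' absorbanceToNitrite(0.5, std)  # 50 uM
#' @export
absorbanceToNitrite <- function(absorbance, standards) {
  stopifnot(is.data.frame(standards),
            all(c("concentration_uM", "absorbance") %in% names(standards)))
  if (nrow(standards) < 3) {
    stop("standard curve needs at least 3 standards")
  }
  fit <- stats::lm(absorbance ~ concentration_uM, data = standards)
  slope <- stats::coef(fit)[["concentration_uM"]]
  intercept <- stats::coef(fit)[["(Intercept)"]]
  if (abs(slope) < .Machine$double.eps) stop("degenerate standard curve (zero slope)")
  out <- (absorbance - intercept) / slope
  attr(out, "r_squared") <- suppressWarnings(summary(fit)$r.squared)
  attr(out, "slope") <- slope
  attr(out, "intercept") <- intercept
  out
}

#' Ammonia oxidation inhibition (AOI\%) profile
#'
#' Computes per-timepoint AOI for one treated condition against its solvent
#' control. The nitrite value recorded immediately before inhibitor addition
#' is subtracted from subsequent measurements to remove pre-treatment
#' activity; for every post-addition timepoint t,
#' \deqn{AOI(t) = 100 (1 - \Delta N_{trt}(t) / \Delta N_{ctl}(t))}
#' where \eqn{\Delta N(t)} is the replicate-mean nitrite increment since the
#' last timepoint at or before the addition time. Values are not clipped:
#' stimulation yields negative AOI and a declining treated culture can exceed
#' 100\%. Replicate uncertainty is propagated by the delta method;
#' per-timepoint significance is a two-sided t-test of replicate-level
#' increments, treated versus control. Timepoints where the control increment
#' does not exceed \code{epsilon} are flagged undefined and excluded from the
#' summaries.
#'
#' @param treated assay data.frame (schema of \code{\link{simulateCulture}})
#'   for the treated replicates of one strain x compound x dose.
#' @param control assay data.frame for the control replicates (same strain
#'   and timepoint grid; the control is interpolated onto the treated grid
#'   otherwise).
#' @param epsilon minimum control increment (uM) for AOI to be defined.
#' @return an \linkS4class{AOIProfile}.
#' @export
computeAoi <- function(treated, control, epsilon = 1) {
  for (d in list(treated, control)) {
    need <- c("replicate", "time_h", "nitrite_uM", "addition_time_h")
    if (!all(need %in% names(d))) {
      stop("assay data must have columns: ", paste(need, collapse = ", "))
    }
  }
  t_add <- unique(treated$addition_time_h)
  if (length(t_add) != 1) stop("treated series must share one addition time")
  times <- sort(unique(treated$time_h))
  t_base <- max(times[times <= t_add])
  if (!is.finite(t_base)) stop("no timepoint at or before the addition time")

  # replicate-level series on the treated grid (interpolating control if needed)
  rep_series <- function(d) {
    reps <- split(d, d$replicate)
    sapply(reps, function(r) {
      r <- r[order(r$time_h), ]
      if (identical(r$time_h, times)) r$nitrite_uM
      else stats::approx(r$time_h, r$nitrite_uM, xout = times, rule = 2)$y
    })
  }
  trt <- rep_series(treated)    # time x replicate
  ctl <- rep_series(control)
  ib <- which(times == t_base)
  dtrt <- sweep(trt, 2, trt[ib, ])   # increments since baseline
  dctl <- sweep(ctl, 2, ctl[ib, ])

  post <- which(times > t_add)
  aoi <- rep(NA_real_, length(post))
  aoi_sd <- rep(NA_real_, length(post))
  pval <- rep(NA_real_, length(post))
  defined <- logical(length(post))
  for (k in seq_along(post)) {
    i <- post[k]
    mt <- mean(dtrt[i, ]); mc <- mean(dctl[i, ])
    if (mc <= epsilon) next
    defined[k] <- TRUE
    aoi[k] <- 100 * (1 - mt / mc)
    # delta method on the ratio of means
    vt <- stats::var(dtrt[i, ]) / ncol(dtrt)
    vc <- stats::var(dctl[i, ]) / ncol(dctl)
    aoi_sd[k] <- 100 * sqrt(vt / mc^2 + (mt^2 / mc^4) * vc)
    pval[k] <- tryCatch(
      stats::t.test(dtrt[i, ], dctl[i, ])$p.value,
      error = function(e) NA_real_   # zero-variance replicates
    )
  }
  tab <- data.frame(time_h = times[post], aoi = aoi, aoi_sd = aoi_sd,
                    p_value = pval, defined = defined)
  def <- which(defined)
  if (length(def) == 0) {
    warning("AOI undefined at every post-addition timepoint (inactive control)")
  }
  endpoint <- if (length(def) > 0) def[length(def)] else NA_integer_
  new("AOIProfile",
      strain = as.character(treated$strain[1] %||% "unknown"),
      compound = as.character(treated$treatment[1] %||% "unknown"),
      dose = as.numeric(treated$dose_mg_per_L[1] %||% NA_real_),
      table = tab,
      summaryEnd = if (is.na(endpoint)) NA_real_ else aoi[endpoint],
      summaryMax = if (length(def) > 0) max(aoi[def]) else NA_real_,
      replicateSd = if (is.na(endpoint)) NA_real_ else aoi_sd[endpoint],
      significant = if (is.na(endpoint)) NA else isTRUE(pval[endpoint] < 0.05),
      pValue = if (is.na(endpoint)) NA_real_ else pval[endpoint])
}

#' AOI profiles for every condition of an assay table
#'
#' Splits a long assay table by strain x treatment x dose, pairs each treated
#' condition with the control series of the same strain and computes its
#' \linkS4class{AOIProfile}.
#'
#' @param assay long assay data.frame (schema of
#'   \code{\link{simulateCulture}}).
#' @param control treatment name of the control series (default "DMSO").
#' @param epsilon minimum control increment (uM).
#' @return data.frame with one row per condition: \code{strain},
#'   \code{compound}, \code{dose_mg_per_L}, \code{aoi_end}, \code{aoi_max},
#'   \code{aoi_sd}, \code{p_value}, plus a list-column \code{profile} of
#'   \linkS4class{AOIProfile} objects.
#' @export
aoiTable <- function(assay, control = "DMSO", epsilon = 1) {
  out <- list()
  for (st in unique(assay$strain)) {
    a <- assay[assay$strain == st, ]
    ctl <- a[a$treatment == control, ]
    if (nrow(ctl) == 0) stop("no ", control, " control series for strain ", st)
    trts <- a[a$treatment != control, ]
    for (cmp in unique(trts$treatment)) {
      for (dose in unique(trts$dose_mg_per_L[trts$treatment == cmp])) {
        tr <- trts[trts$treatment == cmp & trts$dose_mg_per_L == dose, ]
        prof <- computeAoi(tr, ctl, epsilon = epsilon)
        out[[length(out) + 1L]] <- data.frame(
          strain = st, compound = cmp, dose_mg_per_L = dose,
          aoi_end = prof@summaryEnd, aoi_max = prof@summaryMax,
          aoi_sd = prof@replicateSd, p_value = prof@pValue,
          stringsAsFactors = FALSE)
        attr(out[[length(out)]], "profile") <- prof
      }
    }
  }
  res <- do.call(rbind, out)
  attr(res, "profiles") <- lapply(out, attr, "profile")
  res
}

# Dunn's post-hoc test: pairwise z statistics on Kruskal-Wallis ranks with
# tie correction; no installed package provides it, so it lives here.
dunn_posthoc <- function(values, groups, adjust = "bonferroni") {
  groups <- factor(groups)
  n <- length(values)
  r <- rank(values)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  rbar <- tapply(r, groups, mean)
  ni <- table(groups)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ni[[a]] + 1 / ni[[b]]))
    z[k] <- (rbar[[a]] - rbar[[b]]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p_raw = p,
             p_adjusted = stats::p.adjust(p, method = adjust),
             row.names = NULL)
}

#' Nonparametric group comparisons of AOI values
#'
#' For each strain x dose: a Kruskal-Wallis test of AOI across compounds
#' followed by Dunn's post-hoc test with Bonferroni adjustment. Pooled
#' AOA-versus-AOB comparisons (per dose) use the two-sample Wilcoxon rank-sum
#' test; Shapiro-Wilk normality diagnostics of the AOI values are reported
#' alongside.
#'
#' @param aoi data.frame of replicate-level AOI values with columns
#'   \code{strain}, \code{compound}, \code{dose_mg_per_L}, \code{aoi} and
#'   optionally \code{domain} ("AOA"/"AOB"; derived from the strain prefix
#'   when absent).
#' @return list with elements \code{kruskal} (per strain x dose),
#'   \code{dunn} (pairwise table), \code{wilcoxon_domain} (per dose) and
#'   \code{shapiro}.
#' @export
compareGroups <- function(aoi) {
  need <- c("strain", "compound", "dose_mg_per_L", "aoi")
  if (!all(need %in% names(aoi))) {
    stop("aoi table must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(aoi$domain)) {
    aoi$domain <- ifelse(grepl("^AOA", aoi$strain), "AOA",
                         ifelse(grepl("^AOB", aoi$strain), "AOB", NA))
  }
  kr <- list(); dn <- list(); wx <- list(); sh <- list()
  for (st in unique(aoi$strain)) {
    for (dose in unique(aoi$dose_mg_per_L[aoi$strain == st])) {
      d <- aoi[aoi$strain == st & aoi$dose_mg_per_L == dose, ]
      if (length(unique(d$compound)) < 2) {
        stop("need at least 2 compounds per strain x dose for comparisons")
      }
      k <- stats::kruskal.test(d$aoi, factor(d$compound))
      kr[[length(kr) + 1L]] <- data.frame(
        strain = st, dose_mg_per_L = dose,
        statistic = unname(k$statistic), df = unname(k$parameter),
        p_value = k$p.value)
      dtab <- dunn_posthoc(d$aoi, d$compound)
      dtab$strain <- st; dtab$dose_mg_per_L <- dose
      dn[[length(dn) + 1L]] <- dtab
      s <- tryCatch(stats::shapiro.test(d$aoi),
                    error = function(e) list(statistic = NA, p.value = NA))
      sh[[length(sh) + 1L]] <- data.frame(
        strain = st, dose_mg_per_L = dose,
        W = unname(s$statistic), p_value = s$p.value)
    }
  }
  for (dose in unique(aoi$dose_mg_per_L)) {
    d <- aoi[aoi$dose_mg_per_L == dose & !is.na(aoi$domain), ]
    if (length(unique(d$domain)) == 2) {
      w <- stats::wilcox.test(aoi ~ domain, data = d, exact = FALSE)
      wx[[length(wx) + 1L]] <- data.frame(
        dose_mg_per_L = dose, W = unname(w$statistic), p_value = w$p.value)
    }
  }
  list(kruskal = do.call(rbind, kr),
       dunn = do.call(rbind, dn),
       wilcoxon_domain = if (length(wx)) do.call(rbind, wx) else NULL,
       shapiro = do.call(rbind, sh))
}

#' Hierarchically cluster the compound x strain AOI matrix
#'
#' Agglomerative clustering of compounds (rows) and strains (columns) on
#' Euclidean distances, as used for inhibition-profile heatmaps. Missing
#' entries are imputed as 0\% (no observed inhibition) and flagged. Rows and
#' columns are sorted by label before clustering so the result is invariant
#' to input order; dendrograms are also returned serialized as Newick
#' strings.
#'
#' @param aoi_matrix numeric matrix of summary AOI\% (compounds x strains).
#' @param linkage linkage method for \code{\link[stats]{hclust}} (default
#'   "complete").
#' @return list with \code{row_hclust}, \code{col_hclust}, \code{ordered}
#'   (matrix reordered by leaf order), \code{row_newick}, \code{col_newick},
#'   \code{cut_heights}, \code{imputed} (logical matrix).
#' @export
clusterHeatmap <- function(aoi_matrix, linkage = "complete") {
  m <- as.matrix(aoi_matrix)
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("need at least 2 rows and 2 columns to cluster")
  }
  if (is.null(rownames(m))) rownames(m) <- sprintf("row%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("col%02d", seq_len(ncol(m)))
  m <- m[order(rownames(m)), order(colnames(m)), drop = FALSE]
  imputed <- is.na(m)
  if (any(imputed)) m[imputed] <- 0

  rh <- stats::hclust(stats::dist(m, method = "euclidean"), method = linkage)
  ch <- stats::hclust(stats::dist(t(m), method = "euclidean"), method = linkage)
  list(
    row_hclust = rh,
    col_hclust = ch,
    ordered = m[rh$order, ch$order, drop = FALSE],
    row_newick = ape::write.tree(ape::as.phylo(rh)),
    col_newick = ape::write.tree(ape::as.phylo(ch)),
    cut_heights = list(rows = rh$height, cols = ch$height),
    imputed = imputed
  )
}
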
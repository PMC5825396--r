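# In silico pharmacology: pore-block drugs, the hypothetical drug
# library, and population-level evaluation of cross-cell predictions.

#' Remaining conductance fraction under pore block
#'
#' The simple pore-block model: a drug at concentration `conc` leaves a
#' fraction `IC50 / (IC50 + conc)` of the targeted maximal
#' conductance/flux.
#'
#' @param ic50 Half-maximal inhibitory concentration (> 0; any
#'   concentration unit, used consistently with `conc`).
#' @param conc Drug concentration (>= 0).
#' @return Remaining fraction in (0, 1].
#' @examples
#' block_fraction(1, 1)            # 0.5: 50% block at [C] = IC50
#' block_fraction(exp(1), 1)       # 0.731: 27% block of a weaker target
#' @export
block_fraction <- function(ic50, conc) {
  if (any(!is.finite(ic50) | ic50 <= 0)) stop("IC50 must be positive")
  if (any(!is.finite(conc) | conc < 0)) stop("concentration must be >= 0")
  ic50 / (ic50 + conc)
}

#' Define a drug
#'
#' A drug is a set of 1-5 targeted transport pathways with per-target
#' IC50 values, plus a simulation concentration.  By default the
#' concentration is the lowest IC50 among the targets, so the most
#' sensitive ("primary") target is inhibited by exactly 50% and weaker
#' targets by less.
#'
#' @param name Drug name.
#' @param targets Named numeric vector of IC50 values, names being
#'   pathway keys (see [transport_pathways()]).
#' @param conc Concentration; `NULL` uses `min(targets)`.
#' @return A `drug_spec` object.
#' @examples
#' drug("dofetilide-like", c(GKr = 1))             # selective IKr block
#' drug("two-target", c(GKr = 1, GCaL = exp(1)))   # 50% / 27% block
#' @export
drug <- function(name, targets, conc = NULL) {
  if (!is.numeric(targets) || is.null(names(targets)) || !length(targets)) {
    stop("targets must be a named numeric vector of IC50 values")
  }
  if (length(targets) > 5) stop("at most 5 targets per drug")
  bad <- setdiff(names(targets), transport_pathways())
  if (length(bad)) {
    stop("unknown pathway key(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(names(targets))) stop("duplicate target pathway")
  if (any(!is.finite(targets) | targets <= 0)) stop("IC50 must be positive")
  if (is.null(conc)) conc <- min(targets)
  if (!is.finite(conc) || conc < 0) stop("concentration must be >= 0")
  structure(list(name = name, targets = targets, conc = conc),
            class = "drug_spec")
}

#' @export
print.drug_spec <- function(x, ...) {
  blk <- round(100 * (1 - block_fraction(x$targets, x$conc)), 1)
  cat("<drug> ", x$name, " at [C]=", format(x$conc), ": ",
      paste0(names(x$targets), " ", blk, "% block", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Convert a drug to a transport scaling
#'
#' Targeted pathways get their pore-block remaining fraction; all other
#' pathways stay at 1.  The result composes multiplicatively with
#' population scale factors.
#'
#' @param drug A `drug_spec`.
#' @param conc Concentration override (default: the drug's own).
#' @return Transport scaling vector (see [transport_scaling()]).
#' @export
drug_scaling <- function(drug, conc = NULL) {
  stopifnot(inherits(drug, "drug_spec"))
  if (is.null(conc)) conc <- drug$conc
  s <- transport_scaling()
  s[names(drug$targets)] <- block_fraction(drug$targets, conc)
  s
}

#' The hypothetical two-target drug library
#'
#' One drug per ordered (primary, secondary) pair of pathways: the
#' secondary IC50 is `ratio` times the primary (default e = 2.718...),
#' and the concentration is the primary IC50, so every drug blocks its
#' primary target by 50% and its secondary target by about 27%.  Ten
#' pathways give 90 drugs.
#'
#' @param pathways Pathway keys to combine (default: the 10 canonical
#'   pathways excluding the two background currents and the sarcolemmal
#'   Ca2+ pump is *not* excluded - i.e. all 13 minus `GbNa`, `GbCa`,
#'   `GpCa`).
#' @param ratio Secondary/primary IC50 ratio.
#' @return List of `drug_spec`s, length `n * (n - 1)`.
#' @export
hypothetical_drug_library <- function(pathways = NULL, ratio = exp(1)) {
  if (is.null(pathways)) {
    pathways <- setdiff(transport_pathways(), c("GbNa", "GbCa", "GpCa"))
  }
  bad <- setdiff(pathways, transport_pathways())
  if (length(bad)) stop("unknown pathway key(s): ", paste(bad, collapse = ", "))
  if (length(pathways) < 2) stop("need at least 2 pathways")
  out <- list()
  for (p1 in pathways) for (p2 in setdiff(pathways, p1)) {
    tg <- stats::setNames(c(1, ratio), c(p1, p2))
    out[[length(out) + 1L]] <- drug(paste0(p1, "+", p2), tg, conc = 1)
  }
  out
}

#' Read a drug catalog from a delimited file
#'
#' Expected columns: `name`, then up to five pairs `pathway_i`,
#' `ic50_i` (i = 1..5); empty cells mark unused target slots.  The
#' simulation concentration defaults to the lowest IC50 in the row.
#'
#' @param path CSV file path.
#' @return List of `drug_spec`s.
#' @examples
#' catalog <- system.file("extdata", "synthetic_drug_catalog.csv",
#'                        package = "crosscell")
#' drugs <- load_drug_catalog(catalog)
#' drugs[[3]]
#' @export
load_drug_catalog <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"name" %in% names(tab)) stop("catalog needs a 'name' column")
  out <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    tg <- numeric(0)
    for (j in 1:5) {
      pcol <- paste0("pathway_", j); icol <- paste0("ic50_", j)
      if (!pcol %in% names(tab) || !icol %in% names(tab)) next
      pw <- tab[[pcol]][i]; ic <- tab[[icol]][i]
      if (is.na(pw) || pw == "") next
      if (is.na(ic)) {
        stop("row ", i, " (", tab$name[i], "): target '", pw,
             "' has no IC50")
      }
      if (pw %in% names(tg)) {
        stop("row ", i, " (", tab$name[i], "): duplicate pathway '", pw, "'")
      }
      tg[pw] <- ic
    }
    out[[i]] <- tryCatch(drug(tab$name[i], tg),
                         error = function(e) {
                           stop("row ", i, " (", tab$name[i], "): ",
                                conditionMessage(e), call. = FALSE)
                         })
  }
  out
}

# identity-line coefficient of determination: 1 - SS(pred-obs)/SS(obs-mean)
.r2_identity <- function(obs, pred) {
  ok <- is.finite(obs) & is.finite(pred)
  obs <- obs[ok]; pred <- pred[ok]
  1 - sum((pred - obs)^2) / sum((obs - mean(obs))^2)
}

#' Evaluate a drug panel with paired populations
#'
#' For every drug: simulate the source population (under the model's
#' input protocol set) and the target population (baseline protocol)
#' with and without the drug; form per-cell drug-induced change vectors
#' of the source features; translate them with the cross-cell model;
#' and compare against the directly simulated target changes.  Cells
#' that are abnormal or unsegmentable under any required condition are
#' excluded from that drug's summary (count reported).
#'
#' @param source_model,target_model `cell_model`s (source must support
#'   the input protocols).
#' @param cross A fitted `crosscell` model whose input columns match the
#'   protocols in `source_protocols`.
#' @param drugs List of `drug_spec`s.
#' @param scale_factors Population scale-factor matrix (e.g. 100 cells).
#' @param source_protocols Named list of `protocol_spec`s matching the
#'   cross model's input blocks.
#' @param target_protocol Baseline `protocol_spec` of the target cells.
#' @param metrics Target features to summarise (percent change), default
#'   APD90 and CaTA of the target baseline protocol.
#' @param ... Passed to [simulate_population()] (e.g. `record_tail_ms`).
#' @return A `drug_panel` object: data frame with, per drug and metric,
#'   mean/SD percent changes (direct source readout, cross-model
#'   prediction, direct target simulation) plus `n_used`; attribute
#'   `r2` holds across-drug identity-line R-squared of prediction vs
#'   target and source-readout vs target for each metric.
#' @export
simulate_drug_panel <- function(source_model, target_model, cross, drugs,
                                scale_factors, source_protocols,
                                target_protocol, metrics = NULL, ...) {
  stopifnot(inherits(cross, "crosscell"))
  if (is.null(names(source_protocols))) {
    names(source_protocols) <- vapply(source_protocols, `[[`, "", "id")
  }
  tgt_id <- target_protocol$id
  if (is.null(metrics)) {
    metrics <- paste0(tgt_id, ".", c("APD90", "CaTA"))
  }

  run_src <- function(extra) {
    simulate_population(source_model, source_protocols,
                        scale_factors = scale_factors,
                        extra_scaling = extra, ...)
  }
  run_tgt <- function(extra) {
    simulate_population(target_model,
                        stats::setNames(list(target_protocol), tgt_id),
                        scale_factors = scale_factors,
                        extra_scaling = extra, ...)
  }
  ctrl_src <- run_src(NULL)
  ctrl_tgt <- run_tgt(NULL)
  x_pre <- feature_table(ctrl_src$features)
  y_pre <- feature_table(ctrl_tgt$features)

  # source feature columns the cross model expects
  want <- names(cross$x_stats$mean)
  miss <- setdiff(want, colnames(x_pre))
  if (length(miss)) {
    stop("source protocols do not provide the model's input columns: ",
         paste(miss, collapse = ", "))
  }

  src_names <- sub(paste0("^", tgt_id, "\\."), "", metrics)
  rows <- list()
  pred_means <- matrix(NA_real_, length(drugs), length(metrics),
                       dimnames = list(NULL, metrics))
  tgt_means <- pred_means; src_means <- pred_means
  for (k in seq_along(drugs)) {
    dg <- drugs[[k]]
    sc <- drug_scaling(dg)
    drug_src <- run_src(sc)
    drug_tgt <- run_tgt(sc)
    x_post <- feature_table(drug_src$features)
    y_post <- feature_table(drug_tgt$features)

    flagged <- function(res) {
      vapply(seq_len(nrow(scale_factors)), function(i) {
        any(vapply(res$flags, function(fl) length(fl[[i]]) > 0, logical(1)))
      }, logical(1))
    }
    nonpos <- function(m) {
      lg <- cross$x_stats$log
      rowSums(m[, want, drop = FALSE][, lg, drop = FALSE] <= 0,
              na.rm = TRUE) > 0
    }
    bad <- flagged(ctrl_src) | flagged(ctrl_tgt) | flagged(drug_src) |
      flagged(drug_tgt) |
      !stats::complete.cases(x_pre[, want, drop = FALSE]) |
      !stats::complete.cases(x_post[, want, drop = FALSE]) |
      !stats::complete.cases(y_pre) | !stats::complete.cases(y_post) |
      nonpos(x_pre) | nonpos(x_post)
    use <- which(!bad)

    chg <- feature_change(cross, x_pre[use, want, drop = FALSE],
                          x_post[use, want, drop = FALSE])
    pred <- predict(cross, chg, type = "change")

    for (j in seq_along(metrics)) {
      mt <- metrics[j]
      direct_tgt <- 100 * (y_post[use, mt] / y_pre[use, mt] - 1)
      src_col <- paste0(names(source_protocols)[1], ".", src_names[j])
      direct_src <- 100 * (x_post[use, src_col] / x_pre[use, src_col] - 1)
      p <- pred[, mt]
      rows[[length(rows) + 1L]] <- data.frame(
        drug = dg$name, metric = mt, n_used = length(use),
        src_mean = mean(direct_src), src_sd = stats::sd(direct_src),
        pred_mean = mean(p), pred_sd = stats::sd(p),
        tgt_mean = mean(direct_tgt), tgt_sd = stats::sd(direct_tgt),
        stringsAsFactors = FALSE)
      pred_means[k, j] <- mean(p)
      tgt_means[k, j] <- mean(direct_tgt)
      src_means[k, j] <- mean(direct_src)
    }
  }
  tab <- do.call(rbind, rows)
  r2 <- data.frame(
    metric = metrics,
    r2_cross = vapply(seq_along(metrics), function(j)
      .r2_identity(tgt_means[, j], pred_means[, j]), numeric(1)),
    r2_direct = vapply(seq_along(metrics), function(j)
      .r2_identity(tgt_means[, j], src_means[, j]), numeric(1)),
    stringsAsFactors = FALSE)
  structure(tab, r2 = r2, class = c("drug_panel", "data.frame"))
}

#' @export
print.drug_panel <- function(x, ...) {
  cat("<drug_panel> ", length(unique(x$drug)), " drugs x ",
      length(unique(x$metric)), " metrics\n", sep = "")
  print(attr(x, "r2"), row.names = FALSE)
  invisible(x)
}

#' @export
plot.drug_panel <- function(x, metric = NULL, ...) {
  r2 <- attr(x, "r2")
  if (is.null(metric)) metric <- r2$metric[1]
  d <- x[x$metric == metric, ]
  rng <- range(c(d$tgt_mean, d$pred_mean, d$src_mean), finite = TRUE)
  graphics::plot(d$tgt_mean, d$pred_mean, xlim = rng, ylim = rng,
                 xlab = "simulated target change (%)",
                 ylab = "estimated change (%)", main = metric,
                 col = "purple", pch = 1, ...)
  graphics::points(d$tgt_mean, d$src_mean, col = "cyan3", pch = 16)
  graphics::abline(0, 1, col = "grey50")
  graphics::legend("topleft", bty = "n",
                   legend = c(sprintf("cross-model (R2=%.3f)",
                                      r2$r2_cross[r2$metric == metric]),
                              sprintf("direct source (R2=%.3f)",
                                      r2$r2_direct[r2$metric == metric])),
                   col = c("purple", "cyan3"), pch = c(1, 16))
  invisible(x)
}
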
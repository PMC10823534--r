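#' Construct a marker panel
#'
#' @param name panel name.
#' @param symbols gene symbols in the panel.
#' @param min_fraction_enriched fraction of panel genes that must be
#'   enriched for the panel to count as matched (default 0.5).
#' @return object of class `csa_panel`.
#' @export
marker_panel <- function(name, symbols, min_fraction_enriched = 0.5) {
  symbols <- unique(toupper(symbols))
  stopifnot(length(symbols) > 0, min_fraction_enriched > 0,
            min_fraction_enriched <= 1)
  structure(list(name = name, symbols = symbols,
                 min_fraction_enriched = min_fraction_enriched),
            class = "csa_panel")
}

#' Default endothelial marker panels
#'
#' The panels used to annotate clusters: pan-endothelial surface markers
#' (PECAM1, KDR, CDH5), vascular-EC markers (CD34, PLVAP), lymphatic-EC
#' markers (CCL21, PROX1, LYVE1), and the five mitosis/cytokinesis
#' markers that define a proliferating cluster (AURKB, MKI67, INCENP,
#' BIRC5, CDCA8 — "CDCNA8" in some listings is an alias of CDCA8).
#'
#' @return named list of [marker_panel()] objects
#'   (EC, VEC, LEC, proliferation).
#' @export
default_marker_panels <- function() {
  list(
    EC = marker_panel("EC", c("PECAM1", "KDR", "CDH5")),
    VEC = marker_panel("VEC", c("CD34", "PLVAP")),
    LEC = marker_panel("LEC", c("CCL21", "PROX1", "LYVE1")),
    proliferation = marker_panel("proliferation",
                                 c("AURKB", "MKI67", "INCENP", "BIRC5",
                                   "CDCA8"), min_fraction_enriched = 1)
  )
}

#' Load marker panels from a YAML config file
#'
#' The file maps panel names to symbol lists, e.g.
#' `VEC: [CD34, PLVAP]`. Requires the `yaml` package.
#'
#' @param path YAML file path.
#' @param min_fraction_enriched applied to every panel.
#' @return named list of [marker_panel()] objects.
#' @export
read_marker_panels <- function(path, min_fraction_enriched = 0.5) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading panel config files requires the 'yaml' package")
  }
  cfg <- yaml::read_yaml(path)
  out <- lapply(names(cfg), function(nm) {
    marker_panel(nm, unlist(cfg[[nm]]), min_fraction_enriched)
  })
  stats::setNames(out, names(cfg))
}

# Relaxed panel enrichment rule: surface/class markers are broadly
# expressed, so the fold threshold is lowered from 2 to 1.5.
.panel_thresholds_default <- function() marker_thresholds(fc_min = 1.5)

#' Fraction of a panel's genes enriched in a cluster
#'
#' A panel gene counts as enriched when its marker-table row for the
#' cluster satisfies the (relaxed) panel thresholds: p < 1e-6,
#' fold-change >= 1.5 and expressing fraction > 25% by default. Panel
#' genes absent from the marker table are dropped with a warning; the
#' fraction is over the genes present.
#'
#' @param marker_table a [call_markers()] result covering the panel genes.
#' @param panel a [marker_panel()].
#' @param cluster cluster id.
#' @param thresholds a [marker_thresholds()] list (default: panel rule).
#' @return fraction in \[0, 1\].
#' @export
panel_enrichment <- function(marker_table, panel, cluster,
                             thresholds = .panel_thresholds_default()) {
  stopifnot(inherits(panel, "csa_panel"))
  rows <- marker_table[marker_table$cluster == cluster, ]
  present <- panel$symbols[panel$symbols %in% rows$gene]
  if (length(present) == 0) {
    stop("no gene of panel '", panel$name, "' is in the marker table")
  }
  if (length(present) < length(panel$symbols)) {
    warning(sprintf("panel '%s': %d gene(s) absent from the marker table",
                    panel$name, length(panel$symbols) - length(present)))
  }
  sub <- rows[match(present, rows$gene), ]
  hit <- sub$p < thresholds$p_max & sub$prop_in > thresholds$prop_min &
    sub$fold_change >= thresholds$fc_min
  mean(hit)
}

#' Classify clusters as vascular/lymphatic EC and flag proliferation
#'
#' For each cluster, the VEC and LEC panel fractions are compared: the
#' winning class must reach its panel's `min_fraction_enriched` and be
#' strictly greater than the other; ties or two sub-threshold fractions
#' leave the cluster unassigned. `is_ec` marks clusters whose EC-panel
#' fraction reaches its threshold. `is_proliferating` requires every one
#' of the five proliferation-panel genes to be enriched.
#'
#' @param marker_table a [call_markers()] result.
#' @param panels named list with elements EC, VEC, LEC, proliferation
#'   (default [default_marker_panels()]).
#' @param thresholds panel enrichment thresholds, see [panel_enrichment()].
#' @return data.frame of class `csa_annotation`: one row per cluster with
#'   is_ec, vessel_class ("VEC"/"LEC"/"unassigned"), is_proliferating and
#'   the four panel fractions.
#' @export
classify_clusters <- function(marker_table,
                              panels = default_marker_panels(),
                              thresholds = .panel_thresholds_default()) {
  need <- c("EC", "VEC", "LEC", "proliferation")
  if (!all(need %in% names(panels))) {
    stop("panels must include: ", paste(need, collapse = ", "))
  }
  clusters <- sort(unique(marker_table$cluster))
  rows <- lapply(clusters, function(cl) {
    fr <- vapply(panels[need], function(p) {
      panel_enrichment(marker_table, p, cl, thresholds)
    }, numeric(1))
    vec <- fr[["VEC"]]; lec <- fr[["LEC"]]
    class <- "unassigned"
    if (vec > lec && vec >= panels$VEC$min_fraction_enriched) class <- "VEC"
    if (lec > vec && lec >= panels$LEC$min_fraction_enriched) class <- "LEC"
    data.frame(cluster = cl,
               is_ec = fr[["EC"]] >= panels$EC$min_fraction_enriched,
               vessel_class = class,
               is_proliferating = fr[["proliferation"]] >= 1,
               frac_ec = fr[["EC"]], frac_vec = vec, frac_lec = lec,
               frac_proliferation = fr[["proliferation"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("csa_annotation", "data.frame")
  out
}
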
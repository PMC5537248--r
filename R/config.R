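#' Analysis configuration
#'
#' Bundles the tunable constants of the pipeline so a single object carries
#' them through every stage.  The defaults reproduce the study settings:
#' TOP250 expanded-clone lists, a Spearman screen threshold of 0.75, a
#' log2(CV) cutoff of -5.5 for stable-gene selection, a 10x germline
#' coverage floor with zero non-reference reads, a 100 bp variant
#' clustering window, and a two-cluster patient stratification.
#'
#' @param top_n Number of most-expanded clonotypes in the TOP-N lists.
#' @param screen_rho_threshold Spearman rho above which a pathway passes
#'   the diversity screen.
#' @param log2_cv_cutoff Genes with log2 coefficient of variation strictly
#'   below this value are selected as stable signature genes.
#' @param germline_min_depth Minimum read depth required in the germline
#'   sample for a somatic call to survive filtering.
#' @param cluster_window_bp Window (bp) within which two candidate variants
#'   on one contig are treated as an alignment-artifact cluster and both
#'   removed.
#' @param n_clusters Number of patient clusters cut from the dendrogram.
#' @param seed Optional integer seed recorded in the configuration.
#'
#' @return A list of class `analysis_config`.
#' @examples
#' cfg <- analysis_config()
#' cfg$top_n
#' @export
analysis_config <- function(top_n = 250,
                            screen_rho_threshold = 0.75,
                            log2_cv_cutoff = -5.5,
                            germline_min_depth = 10,
                            cluster_window_bp = 100,
                            n_clusters = 2,
                            seed = NULL) {
  stopifnot(is.numeric(top_n), length(top_n) == 1L, top_n >= 1)
  for (v in list(screen_rho_threshold, log2_cv_cutoff, germline_min_depth,
                 cluster_window_bp, n_clusters)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("all configuration thresholds must be finite scalars")
    }
  }
  structure(list(
    top_n = as.integer(top_n),
    screen_rho_threshold = screen_rho_threshold,
    log2_cv_cutoff = log2_cv_cutoff,
    germline_min_depth = germline_min_depth,
    cluster_window_bp = cluster_window_bp,
    n_clusters = as.integer(n_clusters),
    seed = seed
  ), class = "analysis_config")
}

#' Read / write an analysis configuration
#'
#' Configurations are stored as flat YAML key-value files so a run is fully
#' described by one small text document.
#'
#' @param path File path of the YAML document.
#' @param config An `analysis_config` object.
#' @return `read_analysis_config` returns an `analysis_config`;
#'   `write_analysis_config` returns `path` invisibly.
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(analysis_config, vals[intersect(names(vals),
                                          names(formals(analysis_config)))])
}

#' @rdname read_analysis_config
#' @export
write_analysis_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}
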
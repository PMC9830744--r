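PROBE_PREFIX <- "__probe__"

#' Inject permutation random probes
#'
#' Appends, for every continuous and categorical original feature, one
#' probe column holding an independent random permutation of that
#' feature's values: the probe keeps the marginal distribution but carries
#' no association with the outcome. Probes derived from boolean features
#' are not generated, since a permuted binary column leaves many values in
#' place and can attain spuriously high importance. Probe names are
#' namespaced as `__probe__<source>`; the caller regenerates probes on
#' each bootstrap iteration by passing a fresh seed.
#'
#' @param ds A [survival_dataset()] with at least one non-boolean feature.
#' @param seed Integer seed for the permutations.
#' @return The augmented `survival_dataset`; restricting it to the original
#'   columns reproduces the input exactly.
#' @export
inject_probes <- function(ds, seed = 1L) {
  eligible <- vapply(ds$meta, function(mt)
    !mt$is_probe && mt$kind != "boolean", logical(1))
  if (!any(eligible))
    stop("probe thresholding unavailable: all features are boolean")
  src <- feature_names(ds)[eligible]
  m <- n_samples(ds)
  probe_cols <- with_seed(seed, vapply(src, function(nm)
    ds$features[sample.int(m), nm], numeric(m)))
  colnames(probe_cols) <- paste0(PROBE_PREFIX, src)
  probe_meta <- lapply(src, function(nm) {
    mt <- ds$meta[[nm]]
    feature_meta(paste0(PROBE_PREFIX, nm), mt$kind, levels = mt$levels,
                 is_probe = TRUE, probe_source = nm)
  })
  names(probe_meta) <- colnames(probe_cols)
  structure(list(features = cbind(ds$features, probe_cols),
                 meta = c(ds$meta, probe_meta),
                 time = ds$time, event = ds$event),
            class = "survival_dataset")
}

#' @rdname inject_probes
#' @export
strip_probes <- function(ds) subset_features(ds, original_features(ds))

#' @rdname inject_probes
#' @param names Character vector of feature names.
#' @export
is_probe_name <- function(names) startsWith(names, PROBE_PREFIX)
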
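#' Save or load a tractica container
#'
#' The native container is a versioned serialized file holding one of the
#' package's objects (connectivity matrix, component set, seed/target space,
#' parcellation, ...) together with format metadata. Loading re-validates the
#' object's invariants so a corrupted file is rejected rather than silently
#' accepted.
#'
#' @param obj Object to save.
#' @param path File path (conventionally `.tractica.rds`).
#' @return `save_container()` returns `path` invisibly; `load_container()`
#'   returns the restored object.
#' @export
save_container <- function(obj, path) {
  cls <- class(obj)[1L]
  if (!startsWith(cls, "tractica_"))
    stop("not a tractica object: ", cls)
  validate_container_payload(obj)
  saveRDS(list(format = "tractica-container", version = 1L,
               class = cls, payload = obj), path)
  invisible(path)
}

#' @rdname save_container
#' @export
load_container <- function(path) {
  raw <- readRDS(path)
  for (field in c("format", "version", "class", "payload")) {
    if (is.null(raw[[field]]))
      stop("container missing metadata field '", field, "'")
  }
  if (!identical(raw$format, "tractica-container"))
    stop("not a tractica container (field 'format')")
  if (raw$version > 1L)
    stop("container version ", raw$version,
         " newer than supported (field 'version')")
  obj <- raw$payload
  if (!identical(class(obj)[1L], raw$class))
    stop("container class metadata mismatch (field 'class')")
  validate_container_payload(obj)
  obj
}

validate_container_payload <- function(obj) {
  if (inherits(obj, "tractica_connmat")) {
    if (is.null(obj$weighting) || is.null(obj$n_subjects_averaged))
      stop("connectivity matrix missing field 'weighting'")
    if (nrow(obj$values) != obj$seed_space$n_seeds ||
        ncol(obj$values) != obj$target_space$n_targets)
      stop("connectivity matrix shape metadata corrupted (field 'values')")
    vr <- range_finite(obj$values)
    if (vr[1L] < 0) stop("connectivity values corrupted: negative entries")
  } else if (inherits(obj, "tractica_components")) {
    if (is.null(obj$K) || is.null(obj$gm_maps))
      stop("component set missing field 'K'")
    if (nrow(obj$gm_maps) != obj$K)
      stop("component set shape metadata corrupted (field 'gm_maps')")
    if (!is.null(obj$wm_maps) && nrow(obj$wm_maps) != obj$K)
      stop("component set shape metadata corrupted (field 'wm_maps')")
  } else if (inherits(obj, "tractica_seed_space")) {
    if (obj$n_seeds != length(obj$seed_ids))
      stop("seed space metadata corrupted (field 'seed_ids')")
  } else if (inherits(obj, "tractica_parcellation")) {
    if (is.null(obj$labels) || is.null(obj$K))
      stop("parcellation missing field 'labels'")
    if (any(obj$labels < 0L | obj$labels > obj$K))
      stop("parcellation labels corrupted (field 'labels')")
  }
  invisible(TRUE)
}
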
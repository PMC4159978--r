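#' Read and write phantom / corruption specifications as JSON
#'
#' Round-trips the generative specifications so simulations are fully
#' described by plain-text files alongside their outputs.
#'
#' @param spec A [phantom_spec] or [corruption_spec].
#' @param path JSON file path.
#' @return `read_*` return the spec object; `write_*` return `path`
#'   invisibly.
#' @name spec_json
NULL

#' @rdname spec_json
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname spec_json
#' @export
read_phantom_spec <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  geometry <- lapply(seq_len(nrow(x$geometry)), function(i)
    list(label = x$geometry$label[i],
         center = unlist(x$geometry$center[i]),
         semi_axes = unlist(x$geometry$semi_axes[i])))
  phantom_spec(grid_shape = x$grid_shape,
               tissue_classes = as.data.frame(x$tissue_classes),
               geometry = geometry,
               contrast_labels = x$contrast_labels,
               echo_times = x$echo_times,
               noise_sd = x$noise_sd, noise_model = x$noise_model,
               seed = x$seed)
}

#' @rdname spec_json
#' @export
write_corruption_spec <- function(spec, path) {
  stopifnot(inherits(spec, "corruption_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname spec_json
#' @export
read_corruption_spec <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  corruption_spec(target_contrast = x$target_contrast,
                  target_echoes = x$target_echoes,
                  line_fraction = x$line_fraction,
                  max_phase_error_rad = x$max_phase_error_rad,
                  corruption_axis = x$corruption_axis,
                  center_exclude = x$center_exclude,
                  seed = x$seed)
}
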
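#' Load the anthropometry fixture
#'
#' Reads the embedded 50th-percentile adult-female anthropometric constants
#' (segment lengths/masses/inertias, glenohumeral centre, torso stadium
#' dimensions, dynamometer contact distances). A different file with the same
#' schema can be supplied to swap populations.
#'
#' @param path path to an anthropometry JSON file; defaults to the fixture
#'   shipped with the package.
#' @return a nested list.
#' @export
default_anthropometry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "anthropometry_f50.json",
                        package = "reconarm", mustWork = TRUE)
  }
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# Inertia tensor of a long segment from mass, length and gyration fractions.
# Long axis is -y; transverse axes x, z.
segment_inertia <- function(seg) {
  it <- seg$mass * (seg$rg_trans_frac * seg$length)^2
  il <- seg$mass * (seg$rg_long_frac * seg$length)^2
  diag(c(it, il, it))
}
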
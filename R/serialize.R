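MODEL_FORMAT <- "reconarm-model"
MODEL_FORMAT_VERSION <- "1.0"

#' Serialize a model to its JSON document form
#'
#' The document format is versioned and carries an explicit units block; the
#' normative schema ships at `inst/schema/model-schema.json`. Writing is
#' deterministic (fixed field order, full numeric precision), so identical
#' models produce byte-identical documents and round-trips are lossless.
#'
#' @param model a [model_variant()].
#' @return a JSON string (class `json`).
#' @export
model_to_json <- function(model) {
  doc <- list(
    format = MODEL_FORMAT,
    version = MODEL_FORMAT_VERSION,
    units = list(length = "m", mass = "kg", angle = "rad", force = "N",
                 inertia = "kg.m^2"),
    variant = model$variant,
    bodies = lapply(unname(model$bodies), function(b) {
      out <- list(name = b$name, mass = b$mass, com = b$com,
                  inertia = lapply(seq_len(3), function(i) b$inertia[i, ]))
      if (!is.null(b$parent)) {
        j <- b$joint
        out$parent <- b$parent
        out$joint <- list(name = j$name, axes = j$axes,
                          coords = as.list(j$coords),
                          range_min = j$range[1, ], range_max = j$range[2, ],
                          offset_p = j$offset_p,
                          offset_R = lapply(seq_len(3), function(i) j$offset_R[i, ]))
      }
      out
    }),
    muscles = lapply(unname(model$muscles), function(m) {
      out <- list(name = m$name, compartment = m$compartment,
                  fmax = m$fmax, lopt = m$lopt,
                  points = lapply(m$points, function(p)
                    list(body = p$body, location = p$location)))
      if (!is.null(m$wrap)) {
        out$wrap <- m$wrap
        out$wrap_segment <- m$wrap_segment
      }
      out
    }),
    wraps = lapply(names(model$wraps), function(id) {
      w <- model$wraps[[id]]
      list(id = id, body = w$body, center = w$center, axis = w$axis,
           radius = w$radius, half_length = w$half_length,
           wrap_side = w$wrap_side, applies_to = as.list(w$applies_to))
    }),
    hand_point = list(body = model$hand_point$body,
                      location = model$hand_point$location)
  )
  jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Write a model document to disk
#' @param model a [model_variant()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  writeLines(model_to_json(model), path)
  invisible(path)
}

#' Read a model document
#' @param path path to a model JSON document.
#' @return a [model_variant()].
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, MODEL_FORMAT)) {
    stop("not a ", MODEL_FORMAT, " document: ", path)
  }
  num <- function(x) as.numeric(unlist(x))
  bodies <- lapply(doc$bodies, function(b) {
    joint <- NULL
    if (!is.null(b$parent)) {
      j <- b$joint
      joint <- joint_spec(j$name, lapply(j$axes, num),
                          as.character(unlist(j$coords)),
                          rbind(num(j$range_min), num(j$range_max)),
                          offset_p = num(j$offset_p),
                          offset_R = do.call(rbind, lapply(j$offset_R, num)))
    }
    rigid_body(b$name, b$mass, num(b$com),
               do.call(rbind, lapply(b$inertia, num)),
               parent = b$parent, joint = joint)
  })
  muscles <- lapply(doc$muscles, function(m) {
    muscle_path(m$name, m$compartment,
                lapply(m$points, function(p)
                  list(body = p$body, location = num(p$location))),
                wrap = m$wrap,
                wrap_segment = if (is.null(m$wrap_segment)) 1L else m$wrap_segment,
                fmax = m$fmax, lopt = m$lopt)
  })
  wraps <- list()
  for (w in doc$wraps) {
    wraps[[w$id]] <- wrap_cylinder(w$body, num(w$center), num(w$axis),
                                   w$radius, w$half_length,
                                   wrap_side = num(w$wrap_side),
                                   applies_to = as.character(unlist(w$applies_to)))
  }
  model_variant(doc$variant, bodies, muscles, wraps,
                hand_point = list(body = doc$hand_point$body,
                                  location = num(doc$hand_point$location)))
}

#' Build and write the three fixture model documents
#'
#' Writes `lumpectomy.json`, `implant.json` and `flap.json` to a directory.
#' Output is deterministic: identical inputs give byte-identical documents.
#'
#' @param dir output directory (created if missing).
#' @param anthro anthropometry fixture.
#' @return named character vector of the written paths.
#' @export
build_fixture_models <- function(dir, anthro = default_anthropometry()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  variants <- c("lumpectomy", "implant", "flap")
  paths <- vapply(variants, function(v) {
    p <- file.path(dir, paste0(v, ".json"))
    write_model(build_variant_model(v, anthro), p)
    p
  }, character(1))
  paths
}
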
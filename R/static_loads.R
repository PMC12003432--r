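#' External point load
#'
#' @param body body the load acts on.
#' @param point application point, body frame (m).
#' @param force force vector, ground frame (N).
#' @return object of class `external_load`.
#' @export
external_load <- function(body, point, force) {
  force <- as.numeric(force)
  if (any(!is.finite(force))) stop("external load force must be finite")
  structure(list(body = body, point = as.numeric(point), force = force),
            class = "external_load")
}

#' Static inverse dynamics
#'
#' With zero velocities and accelerations the equations of motion reduce to
#' tau = -(sum_loads J' F + G): the generalized moment the musculature must
#' supply per coordinate to hold the posture against the external loads and
#' gravity.
#'
#' @param model a [model_variant()].
#' @param q posture.
#' @param loads list of [external_load()] objects.
#' @param g gravity vector (m/s^2).
#' @return named numeric vector of joint moments (N m).
#' @export
static_joint_moments <- function(model, q, loads = list(),
                                 g = c(0, -9.80665, 0)) {
  if (inherits(loads, "external_load")) loads <- list(loads)
  fk <- forward_kinematics(model, q)
  tau <- -gravity_generalized_forces(model, q, g)
  for (ld in loads) {
    if (!ld$body %in% names(model$bodies)) {
      stop("external load on unknown body: ", ld$body)
    }
    J <- point_jacobian(model, q, ld$body, ld$point, fk = fk)
    tau <- tau - as.numeric(t(J) %*% ld$force)
  }
  names(tau) <- model$coords
  tau
}

#' Strength-test configuration for a validation posture
#'
#' Returns the documented test posture, the dynamometer contact point and the
#' unit load direction (opposing the tested motion), plus the primary
#' coordinate evaluated for that test. Contact distances come from the
#' anthropometry fixture: for external/internal rotation the dynamometer sits
#' on the distal forearm (elbow flexed 90 degrees, shoulder neutral, load
#' horizontal); for the planar tests the arm is at 90 degrees elevation with
#' the contact on the proximal forearm of the extended limb.
#'
#' @param label one of "external_rotation", "internal_rotation",
#'   "horizontal_adduction", "horizontal_abduction", "elevation".
#' @param anthro anthropometry fixture list.
#' @return list with `posture` (named angles, rad), `body`, `point`,
#'   `direction` (unit ground-frame load direction), `primary` coordinate.
#' @export
validation_posture <- function(label, anthro = default_anthropometry()) {
  labels <- c("external_rotation", "internal_rotation",
              "horizontal_adduction", "horizontal_abduction", "elevation")
  label <- match.arg(label, labels)
  d_rot <- anthro$dynamometer$rotation_contact_forearm
  d_pl <- anthro$dynamometer$planar_contact_from_gh -
    anthro$segments$humerus$length
  q <- c(elv_plane = 0, elv_angle = 0, axial_rotation = 0, elbow_flexion = 0)
  switch(label,
    external_rotation = {
      q["elbow_flexion"] <- pi / 2
      list(posture = q, body = "forearm", point = c(0, -d_rot, 0),
           direction = c(0, 0, -1), primary = "axial_rotation")
    },
    internal_rotation = {
      q["elbow_flexion"] <- pi / 2
      list(posture = q, body = "forearm", point = c(0, -d_rot, 0),
           direction = c(0, 0, 1), primary = "axial_rotation")
    },
    horizontal_abduction = {
      q["elv_angle"] <- pi / 2
      list(posture = q, body = "forearm", point = c(0, -d_pl, 0),
           direction = c(1, 0, 0), primary = "elv_plane")
    },
    horizontal_adduction = {
      q["elv_angle"] <- pi / 2
      list(posture = q, body = "forearm", point = c(0, -d_pl, 0),
           direction = c(-1, 0, 0), primary = "elv_plane")
    },
    elevation = {
      q["elv_plane"] <- deg2rad(30)
      q["elv_angle"] <- pi / 2
      list(posture = q, body = "forearm", point = c(0, -d_pl, 0),
           direction = c(0, -1, 0), primary = "elv_angle")
    })
}

#' Cohort strength table
#'
#' Group-mean dynamometer forces (N, mean and SD) for the three surgical
#' groups in the five test postures, with the measured shoulder moments
#' (N m) they correspond to. Group sizes: lumpectomy n = 9, implant n = 9,
#' flap n = 7.
#'
#' @param path optional CSV path; defaults to the table shipped with the
#'   package.
#' @return data.frame with columns group, posture, n, force_mean_N,
#'   force_sd_N, moment_mean_Nm, moment_sd_Nm.
#' @export
strength_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "strength_cohort.csv",
                        package = "reconarm", mustWork = TRUE)
  }
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("group", "posture", "n", "force_mean_N", "force_sd_N",
              "moment_mean_Nm", "moment_sd_Nm")
  if (!all(needed %in% names(tb))) stop("strength table missing columns")
  if (any(tb$force_sd_N < 0) || any(tb$moment_sd_Nm < 0)) {
    stop("strength SDs must be non-negative")
  }
  tb
}

#' Predicted joint moment for one group x posture cell
#'
#' @param model the group's [model_variant()].
#' @param label validation posture label.
#' @param force applied dynamometer force magnitude (N).
#' @param anthro anthropometry fixture.
#' @param g gravity vector.
#' @return predicted moment (N m, magnitude) about the primary coordinate.
#' @export
predicted_moment <- function(model, label, force,
                             anthro = default_anthropometry(),
                             g = c(0, -9.80665, 0)) {
  cfg <- validation_posture(label, anthro)
  load <- external_load(cfg$body, cfg$point, force * cfg$direction)
  tau <- static_joint_moments(model, cfg$posture, list(load), g = g)
  abs(tau[[cfg$primary]])
}

#' Run the full 15-cell validation
#'
#' Predicts the primary-coordinate shoulder moment for every group x posture
#' cell under the group-mean external load and compares it against the
#' measured moment mean +/- SD.
#'
#' @param models named list of the three variant models (names lumpectomy,
#'   implant, flap); built if omitted.
#' @param strength strength table (see [strength_table()]).
#' @param anthro anthropometry fixture.
#' @return data.frame of validation rows with predicted moment and
#'   within_1sd / within_2sd flags.
#' @export
run_validation <- function(models = NULL, strength = strength_table(),
                           anthro = default_anthropometry()) {
  if (is.null(models)) {
    models <- list(lumpectomy = build_variant_model("lumpectomy", anthro),
                   implant = build_variant_model("implant", anthro),
                   flap = build_variant_model("flap", anthro))
  }
  rows <- lapply(seq_len(nrow(strength)), function(i) {
    r <- strength[i, ]
    model <- models[[r$group]]
    if (is.null(model)) stop("missing model for group: ", r$group)
    pred <- predicted_moment(model, r$posture, r$force_mean_N, anthro)
    dev <- abs(pred - r$moment_mean_Nm)
    data.frame(group = r$group, posture = r$posture,
               predicted_Nm = pred,
               measured_mean_Nm = r$moment_mean_Nm,
               measured_sd_Nm = r$moment_sd_Nm,
               within_1sd = dev <= r$moment_sd_Nm,
               within_2sd = dev <= 2 * r$moment_sd_Nm)
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- c(n_within_1sd = sum(out$within_1sd),
                            n_within_2sd = sum(out$within_2sd),
                            n_total = nrow(out))
  out
}
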
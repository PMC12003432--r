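# Fixture muscle geometry.
#
# Right-arm attachment coordinates (m). Frames: thorax origin at the
# suprasternal notch (x anterior, y superior, z right; scapula and clavicle
# sites are fixed to the thorax since shoulder-girdle kinematics are out of
# scope); humerus origin at the glenohumeral centre; forearm origin at the
# elbow centre; long axes point along -y at zero pose. Coordinates were
# calibrated once (scripts/calibrate_fixture.R) so compartment moment arms
# fall in the literature envelope, then frozen. fmax values are young-adult
# reference maxima; the builder applies the female scale factor.
muscle_fixture_table <- function() {
  pt <- function(body, x, y, z) list(body = body, location = c(x, y, z))
  list(
    list(name = "delt_anterior", compartment = "deltoid, anterior",
         fmax = 1218, lopt = 0.098,
         points = list(pt("thorax", 0.022, -0.012, 0.125),
                       pt("thorax", 0.010, -0.005, 0.187),
                       pt("humerus", 0.006, -0.130, 0.012))),
    list(name = "delt_middle", compartment = "deltoid, middle",
         fmax = 1103, lopt = 0.108,
         points = list(pt("thorax", -0.028, 0.005, 0.190),
                       pt("thorax", 0.002, 0.000, 0.196),
                       pt("humerus", 0.000, -0.130, 0.012))),
    list(name = "delt_posterior", compartment = "deltoid, posterior",
         fmax = 201, lopt = 0.137,
         points = list(pt("thorax", -0.065, -0.005, 0.155),
                       pt("humerus", -0.018, -0.025, 0.015),
                       pt("humerus", 0.004, -0.125, 0.010))),
    list(name = "supraspinatus", compartment = "rotator cuff",
         fmax = 499, lopt = 0.068,
         points = list(pt("thorax", -0.070, -0.015, 0.105),
                       pt("humerus", 0.003, 0.026, 0.008),
                       pt("humerus", 0.008, 0.014, 0.020))),
    list(name = "infraspinatus", compartment = "rotator cuff",
         fmax = 1210, lopt = 0.076,
         points = list(pt("thorax", -0.085, -0.055, 0.105),
                       pt("humerus", -0.022, 0.002, 0.010),
                       pt("humerus", -0.010, 0.008, 0.020))),
    list(name = "subscapularis", compartment = "rotator cuff",
         fmax = 1377, lopt = 0.087,
         points = list(pt("thorax", -0.065, -0.055, 0.095),
                       pt("humerus", 0.020, 0.000, 0.006),
                       pt("humerus", 0.016, 0.006, 0.008))),
    list(name = "teres_minor", compartment = "rotator cuff",
         fmax = 354, lopt = 0.074,
         points = list(pt("thorax", -0.080, -0.090, 0.125),
                       pt("humerus", -0.016, -0.004, 0.016))),
    list(name = "teres_major", compartment = "teres major",
         fmax = 425, lopt = 0.162,
         points = list(pt("thorax", -0.085, -0.125, 0.115),
                       pt("humerus", 0.005, -0.055, -0.005))),
    list(name = "pec_major_clavicular",
         compartment = "pectoralis major, clavicular",
         fmax = 364, lopt = 0.144,
         points = list(pt("thorax", 0.020, -0.020, 0.055),
                       pt("thorax", 0.045, -0.060, 0.115),
                       pt("humerus", 0.020, -0.065, 0.004))),
    list(name = "pec_major_sternal",
         compartment = "pectoralis major, sternal",
         fmax = 515, lopt = 0.138,
         points = list(pt("thorax", 0.025, -0.085, 0.012),
                       pt("thorax", 0.050, -0.100, 0.105),
                       pt("humerus", 0.020, -0.075, 0.003))),
    list(name = "pec_major_ribs", compartment = "pectoralis major, ribs",
         fmax = 390, lopt = 0.138,
         points = list(pt("thorax", 0.022, -0.135, 0.020),
                       pt("thorax", 0.048, -0.125, 0.105),
                       pt("humerus", 0.020, -0.085, 0.003))),
    list(name = "lat_dorsi_thoracic", compartment = "latissimus dorsi, thoracic",
         fmax = 290, lopt = 0.264,
         points = list(pt("thorax", -0.095, -0.150, 0.055),
                       pt("thorax", -0.020, -0.120, 0.130),
                       pt("humerus", 0.006, -0.050, -0.006))),
    list(name = "lat_dorsi_lumbar", compartment = "latissimus dorsi, lumbar",
         fmax = 317, lopt = 0.253,
         points = list(pt("thorax", -0.095, -0.230, 0.035),
                       pt("thorax", -0.020, -0.130, 0.135),
                       pt("humerus", 0.006, -0.055, -0.006))),
    list(name = "coracobrachialis", compartment = "coracobrachialis",
         fmax = 242, lopt = 0.093,
         points = list(pt("thorax", 0.015, -0.025, 0.135),
                       pt("humerus", 0.002, -0.115, 0.000))),
    list(name = "biceps_long", compartment = "biceps brachii, long head",
         fmax = 525, lopt = 0.116,
         points = list(pt("thorax", 0.005, -0.012, 0.155),
                       pt("humerus", 0.012, -0.015, 0.008),
                       pt("humerus", 0.012, -0.280, 0.002),
                       pt("forearm", 0.008, -0.035, 0.002))),
    list(name = "biceps_short", compartment = "biceps brachii, short head",
         fmax = 316, lopt = 0.132,
         points = list(pt("thorax", 0.018, -0.028, 0.132),
                       pt("humerus", 0.010, -0.280, 0.000),
                       pt("forearm", 0.008, -0.035, 0.002))),
    list(name = "triceps_long", compartment = "triceps brachii, long head",
         fmax = 771, lopt = 0.134,
         points = list(pt("thorax", -0.015, -0.040, 0.150),
                       pt("humerus", -0.015, -0.280, 0.000),
                       pt("forearm", -0.022, 0.015, 0.000))),
    list(name = "triceps_lateral", compartment = "triceps brachii, lateral head",
         fmax = 717, lopt = 0.114,
         points = list(pt("humerus", -0.008, -0.090, 0.012),
                       pt("humerus", -0.015, -0.280, 0.004),
                       pt("forearm", -0.022, 0.015, 0.002))),
    list(name = "triceps_medial", compartment = "triceps brachii, medial head",
         fmax = 717, lopt = 0.114,
         points = list(pt("humerus", -0.008, -0.140, -0.006),
                       pt("humerus", -0.015, -0.280, -0.003),
                       pt("forearm", -0.022, 0.015, -0.002))),
    list(name = "brachialis", compartment = "brachialis",
         fmax = 987, lopt = 0.086,
         points = list(pt("humerus", 0.010, -0.200, 0.000),
                       pt("forearm", 0.004, -0.025, 0.000))),
    list(name = "brachioradialis", compartment = "brachioradialis",
         fmax = 262, lopt = 0.173,
         points = list(pt("humerus", 0.006, -0.270, 0.008),
                       pt("forearm", 0.015, -0.220, 0.015)))
  )
}

#' Build the articulated model for one surgical variant
#'
#' Assembles the thorax-humerus-forearm-hand chain (4 coordinates: elevation
#' plane, elevation angle, axial rotation, elbow flexion), the muscle path
#' set, the torso mass properties for the variant's tissue-density scheme,
#' and, for the implant variant, the 405-cc wrap cylinder (with the
#' intermediate sternal/ribs via points removed so the paths interact with
#' the surface).
#'
#' @param variant "lumpectomy", "implant" or "flap".
#' @param anthro anthropometry list from [default_anthropometry()].
#' @param implant_volume implant volume (cc); only used for the implant
#'   variant.
#' @param implant_projection implant projection (cm).
#' @return a [model_variant()].
#' @export
build_variant_model <- function(variant,
                                anthro = default_anthropometry(),
                                implant_volume = NULL,
                                implant_projection = NULL) {
  variant <- match.arg(variant, c("lumpectomy", "implant", "flap"))
  torso <- build_variant_torso(variant, anthro)
  segs <- anthro$segments
  hum <- segs$humerus; fa <- segs$forearm; hd <- segs$hand

  shoulder <- joint_spec(
    name = "shoulder",
    axes = list(c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0)),
    coords = c("elv_plane", "elv_angle", "axial_rotation"),
    range = cbind(deg2rad(c(-95, 130)), deg2rad(c(-10, 180)),
                  deg2rad(c(-100, 100))),
    offset_p = anthro$gh_center)
  elbow <- joint_spec(
    name = "elbow",
    axes = list(c(0, 0, 1)),
    coords = "elbow_flexion",
    range = cbind(deg2rad(c(-5, 150))),
    offset_p = c(0, -hum$length, 0))
  # hand welded to the forearm: the wrist is not a modeled degree of freedom
  wrist <- joint_spec(
    name = "wrist_weld",
    axes = list(),
    coords = character(0),
    range = matrix(numeric(0), nrow = 2, ncol = 0),
    offset_p = c(0, -fa$length, 0))

  bodies <- list(
    rigid_body("thorax", torso$mass, torso$com, torso$inertia),
    rigid_body("humerus", hum$mass, c(0, -hum$com_frac * hum$length, 0),
               segment_inertia(hum), parent = "thorax", joint = shoulder),
    rigid_body("forearm", fa$mass, c(0, -fa$com_frac * fa$length, 0),
               segment_inertia(fa), parent = "humerus", joint = elbow),
    rigid_body("hand", hd$mass, c(0, -hd$com_frac * hd$length, 0),
               segment_inertia(hd), parent = "forearm", joint = wrist)
  )

  scale <- anthro$fmax_female_scale
  wraps <- list()
  muscles <- lapply(muscle_fixture_table(), function(m) {
    pts <- m$points
    wrap <- NULL; wseg <- 1L
    if (variant == "implant" &&
        m$name %in% c("pec_major_sternal", "pec_major_ribs")) {
      # remove intermediate via points between origin and insertion
      pts <- pts[c(1, length(pts))]
      wrap <- "implant"
    }
    muscle_path(m$name, m$compartment, pts, wrap = wrap, wrap_segment = wseg,
                fmax = scale * m$fmax, lopt = m$lopt)
  })
  if (variant == "implant") {
    vol <- if (is.null(implant_volume)) anthro$implant$volume_cc else implant_volume
    proj <- if (is.null(implant_projection)) anthro$implant$projection_cm else implant_projection
    wraps <- list(implant = implant_wrap_from_spec(vol, proj))
  }

  model_variant(variant, bodies, muscles, wraps,
                hand_point = list(body = "hand",
                                  location = as.numeric(anthro$hand_point)))
}
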
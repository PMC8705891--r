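# Anthropometric scaling of the generic model from a quasi-static marker
# trial, using surface marker positions and calculated joint centres.

#' Scale set returned by [scale_model()] for audit
#'
#' @param pelvis_factors numeric `c(depth, width, height)`.
#' @param femur_factor,tibia_factor,foot_factor named numeric
#'   `c(left=, right=)`.
#' @return object of class `scale_set`.
#' @export
scale_set <- function(pelvis_factors, femur_factor, tibia_factor, foot_factor) {
  s <- list(pelvis_factors = pelvis_factors, femur_factor = femur_factor,
            tibia_factor = tibia_factor, foot_factor = foot_factor)
  assert_that(all(unlist(s) > 0), "all scale factors must be strictly positive")
  structure(s, class = "scale_set")
}

#' @export
print.scale_set <- function(x, ...) {
  cat("<scale_set>\n")
  cat("  pelvis (depth, width, height):",
      paste(round(x$pelvis_factors, 4), collapse = ", "), "\n")
  for (f in c("femur_factor", "tibia_factor", "foot_factor")) {
    cat(" ", f, ": left", round(x[[f]][["left"]], 4),
        "right", round(x[[f]][["right"]], 4), "\n")
  }
  invisible(x)
}

#' Scale the generic model to a subject
#'
#' Scale factors are derived from surface marker positions and calculated
#' joint centres in a quasi-static pose: the femur is scaled linearly by the
#' subject's hip-centre-to-knee-centre distance over the generic one, the
#' tibia analogously from knee to ankle centre, the foot from heel-to-toe
#' marker distance, and the pelvis anisotropically (width from the inter-ASIS
#' distance, depth from the ASIS-midpoint-to-sacrum distance, height by the
#' geometric mean of the two). Hip joint centres of the scaled model are
#' re-derived from [hip_joint_centre_regression()] on the subject's pelvic
#' dimensions.
#'
#' When `register_markers = TRUE` (default) the subject's static pose is
#' fitted once by inverse kinematics and every surface marker's model-fixed
#' position is re-registered in its segment frame, the usual final
#' marker-adjustment step of model scaling.
#'
#' @param model a `skeletal_model` (generic or previously scaled).
#' @param static_markers a [marker_trial()] holding one quasi-static pose
#'   (all mandatory markers, any number of frames; frame means are used).
#' @param anthropometry subject [generic_anthropometry()] measurements.
#' @param register_markers re-register marker locations from the static pose.
#' @return list with elements `model` (the scaled `skeletal_model`) and
#'   `scale_set` (a [scale_set()] for audit).
#' @export
scale_model <- function(model, static_markers, anthropometry,
                        register_markers = TRUE) {
  a <- validate_anthropometry(anthropometry)
  .require_markers(static_markers, pig_lower_limb_markers())
  pos <- static_marker_means(static_markers)

  lasi <- pos["LASI", ]; rasi <- pos["RASI", ]; sacr <- pos["SACR", ]
  mid <- (lasi + rasi) / 2
  PW <- vnorm(lasi - rasi)
  assert_that(PW > 1e-6, "degenerate static geometry: zero ASIS breadth")
  Yp <- (lasi - rasi) / PW
  vv <- mid - sacr
  Xp <- vv - sum(vv * Yp) * Yp
  assert_that(vnorm(Xp) > 1e-9,
              "degenerate static geometry: collinear pelvis markers")
  Xp <- unitize(Xp)
  Zp <- cross3(Xp, Yp)
  PD <- vnorm(mid - sacr)

  g <- model$geometry
  f_w <- PW / g$pelvic_width
  f_d <- PD / g$pelvic_depth
  f_h <- sqrt(f_w * f_d)

  d_knee <- a$knee_width / 2 + model$marker_radius
  d_ankle <- a$ankle_width / 2 + model$marker_radius

  fem <- tib <- foo <- c(left = NA_real_, right = NA_real_)
  hjc_new <- list()
  for (side in c("left", "right")) {
    P <- if (side == "right") "R" else "L"
    hl <- hip_joint_centre_regression(PW, PD, side)
    hipc <- mid + hl[1] * Xp + hl[2] * Yp + hl[3] * Zp
    kneec <- chord_joint_centre(hipc, pos[paste0(P, "KNE"), ],
                                pos[paste0(P, "THI"), ], d_knee)
    anklec <- chord_joint_centre(kneec, pos[paste0(P, "ANK"), ],
                                 pos[paste0(P, "TIB"), ], d_ankle)
    fem[side] <- vnorm(hipc - kneec) / g$femur_length[[side]]
    tib[side] <- vnorm(kneec - anklec) / g$tibia_length[[side]]
    foo[side] <- vnorm(pos[paste0(P, "TOE"), ] - pos[paste0(P, "HEE"), ]) /
      (0.9 * g$foot_length[[side]])
    hjc_new[[side]] <- hip_joint_centre_regression(PW, PD, side)
  }

  ss <- scale_set(pelvis_factors = c(depth = f_d, width = f_w, height = f_h),
                  femur_factor = fem, tibia_factor = tib, foot_factor = foo)

  m <- model
  # pelvis: anisotropic, applied component-wise in the pelvis frame
  pf <- c(f_d, f_w, f_h)
  m$segments$pelvis$markers <- lapply(m$segments$pelvis$markers,
                                      function(p) p * pf)
  for (side in c("left", "right")) {
    sfx <- substr(side, 1, 1)
    f_f <- fem[[side]]; f_t <- tib[[side]]; f_o <- foo[[side]]
    m$segments[[paste0("femur_", sfx)]]$origin <- hjc_new[[side]]
    m$segments[[paste0("femur_", sfx)]]$markers <-
      lapply(m$segments[[paste0("femur_", sfx)]]$markers, function(p) p * f_f)
    m$segments[[paste0("tibia_", sfx)]]$origin <-
      m$segments[[paste0("tibia_", sfx)]]$origin * f_f
    m$segments[[paste0("tibia_", sfx)]]$markers <-
      lapply(m$segments[[paste0("tibia_", sfx)]]$markers, function(p) p * f_t)
    m$segments[[paste0("talus_", sfx)]]$origin <-
      m$segments[[paste0("talus_", sfx)]]$origin * f_t
    m$segments[[paste0("foot_", sfx)]]$origin <-
      m$segments[[paste0("foot_", sfx)]]$origin * f_o
    # foot markers scale along the foot axis; their height above the sole is
    # a marker-hardware constant and is left unscaled
    m$segments[[paste0("foot_", sfx)]]$markers <-
      lapply(m$segments[[paste0("foot_", sfx)]]$markers,
             function(p) c(p[1] * f_o, p[2] * f_o, p[3]))
    m$segments[[paste0("toes_", sfx)]]$origin <-
      m$segments[[paste0("toes_", sfx)]]$origin * f_o
    # lateral stand-offs of the joint markers come from the measured widths,
    # not from the longitudinal scale factor
    s_lat <- if (side == "right") -1 else 1
    P <- if (side == "right") "R" else "L"
    m$segments[[paste0("femur_", sfx)]]$markers[[paste0(P, "KNE")]][2] <-
      s_lat * d_knee
    m$segments[[paste0("tibia_", sfx)]]$markers[[paste0(P, "ANK")]][2] <-
      s_lat * d_ankle
  }
  m$geometry <- list(
    femur_length = g$femur_length * fem[c("left", "right")],
    tibia_length = g$tibia_length * tib[c("left", "right")],
    ankle_height = g$ankle_height * foo[c("left", "right")],
    foot_length = g$foot_length * foo[c("left", "right")],
    pelvic_width = PW, pelvic_depth = PD)
  m$anthropometry <- a

  if (register_markers) {
    # fit the static pose on the anatomical markers only (wands excluded):
    # wand placement is arbitrary, so wand locals are calibrated purely by
    # the registration step below
    fit <- solve_frame(m, pos, q0 = NULL, cfg = ik_config(
      marker_weights = c(RTHI = 0, LTHI = 0, RTIB = 0, LTIB = 0)))
    fk <- .fk_core(m, .assign_q(m, fit$q))
    for (sn in names(m$segments)) {
      seg <- m$segments[[sn]]
      if (!length(seg$markers)) next
      Rg <- fk$frames[[sn]]$R; og <- fk$frames[[sn]]$origin
      for (l in names(seg$markers)) {
        if (l %in% rownames(pos)) {
          m$segments[[sn]]$markers[[l]] <- as.numeric(crossprod(Rg, pos[l, ] - og))
        }
      }
    }
  }
  list(model = validate_model(m), scale_set = ss)
}
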
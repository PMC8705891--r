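# Forward kinematics of the constrained chain.
#
# Each segment's pose in its parent is Trans(origin + translational DoFs)
# followed by the ordered product of axis-angle rotations of its rotational
# DoFs (axes expressed in the parent frame at neutral, intrinsic composition).
# Global poses are obtained by composing parent-to-child transforms in
# topological order.

# Map a free-coordinate vector onto per-dof values (locked dofs take their
# stored value, 0 by default). Returns a named list per segment.
.assign_q <- function(model, q) {
  free <- coordinate_names(model)
  assert_that(length(q) == length(free),
              "coordinate vector has length %d but the model has %d free coordinates",
              length(q), length(free))
  if (!is.null(names(q))) {
    assert_that(setequal(names(q), free), "coordinate names do not match the model")
    q <- q[free]
  }
  stats::setNames(as.numeric(q), free)
}

#' Forward kinematics: global marker positions and segment poses
#'
#' Evaluates the pose of every segment and the global position of every
#' model-fixed marker for a given coordinate vector.
#'
#' @param model a `skeletal_model`.
#' @param q numeric vector of free coordinates (radians / metres), optionally
#'   named; length must equal [n_coordinates()].
#' @param check enforce coordinate bounds (default `TRUE`).
#' @return a list with `markers` (matrix, one row per marker, rownames =
#'   labels) and `frames` (per segment: list with rotation `R` and global
#'   `origin`).
#' @export
#' @examples
#' m <- build_generic_model()
#' fk <- forward_kinematics(m, rep(0, n_coordinates(m)))
#' fk$markers["LASI", ]
forward_kinematics <- function(model, q, check = TRUE) {
  qv <- .assign_q(model, q)
  if (check) {
    b <- coordinate_bounds(model)
    bad <- which(qv < b[, "lower"] - 1e-9 | qv > b[, "upper"] + 1e-9)
    assert_that(length(bad) == 0, "coordinate(s) out of bounds: %s",
                paste(names(qv)[bad], collapse = ", "))
  }
  .fk_core(model, qv)
}

# qv: full named free-coordinate vector. Fast path used by the IK inner
# loop. When `dof_info = TRUE`, also returns, per free degree of freedom,
# its instantaneous global axis `w` and joint position `p` (the quantities
# needed for the analytic marker Jacobian: d x_m / d q = w x (x_m - p) for
# rotations, w for translations).
.fk_core <- function(model, qv, marker_labels = NULL, dof_info = FALSE) {
  frames <- vector("list", length(model$segments))
  names(frames) <- names(model$segments)
  mk_pos <- list()
  mk_seg <- character()
  dinfo <- if (dof_info) list() else NULL
  for (seg in model$segments) {
    t_local <- seg$origin
    R_local <- diag(3)
    if (is.na(seg$parent)) {
      Rp <- diag(3); op <- c(0, 0, 0)
    } else {
      p <- frames[[seg$parent]]
      Rp <- p$R; op <- p$origin
    }
    # translations (root joint) first, then ordered rotations
    for (d in seg$dofs) {
      if (d$type == "translation") {
        val <- if (d$locked) d$value else qv[[d$name]]
        t_local <- t_local + d$axis * val
        if (dof_info && !d$locked) {
          dinfo[[d$name]] <- list(type = "translation",
                                  w = as.numeric(Rp %*% d$axis))
        }
      }
    }
    og <- op + as.numeric(Rp %*% t_local)
    R_run <- Rp
    for (d in seg$dofs) {
      if (d$type != "translation") {
        val <- if (d$locked) d$value else qv[[d$name]]
        if (dof_info && !d$locked) {
          dinfo[[d$name]] <- list(type = "rotation",
                                  w = as.numeric(R_run %*% d$axis), p = og)
        }
        if (val != 0) R_run <- R_run %*% rot_axis_angle(d$axis, val)
      }
    }
    Rg <- R_run
    frames[[seg$name]] <- list(R = Rg, origin = og)
    if (length(seg$markers)) {
      keep <- if (is.null(marker_labels)) names(seg$markers) else
        intersect(names(seg$markers), marker_labels)
      if (length(keep)) {
        loc <- matrix(unlist(seg$markers[keep]), nrow = 3)
        pos <- t(Rg %*% loc + og)
        rownames(pos) <- keep
        mk_pos[[seg$name]] <- pos
        mk_seg <- c(mk_seg, stats::setNames(rep(seg$name, length(keep)), keep))
      }
    }
  }
  markers <- do.call(rbind, unname(mk_pos))
  list(markers = markers, frames = frames, dof_info = dinfo,
       marker_segment = mk_seg)
}

# For each segment, the free coordinates that move it (its own and all
# ancestors' unlocked dofs).
.segment_ancestral_dofs <- function(model) {
  out <- list()
  for (seg in model$segments) {
    own <- vapply(Filter(function(d) !d$locked, seg$dofs), `[[`, "", "name")
    inherited <- if (is.na(seg$parent)) character() else out[[seg$parent]]
    out[[seg$name]] <- c(inherited, own)
  }
  out
}

# Forward kinematics over a trajectory: returns segment rotation arrays,
# origins, joint-centre trajectories and marker trajectories. This is the
# "body kinematics" backend shared with the IK engine.
.fk_trajectory <- function(model, q_traj) {
  stopifnot(is.matrix(q_traj))
  nf <- nrow(q_traj)
  seg_names <- names(model$segments)
  R_arr <- lapply(seg_names, function(s) array(NA_real_, c(3, 3, nf)))
  names(R_arr) <- seg_names
  O_arr <- lapply(seg_names, function(s) matrix(NA_real_, nf, 3))
  names(O_arr) <- seg_names
  labels <- model_marker_labels(model)
  M_arr <- lapply(labels, function(l) matrix(NA_real_, nf, 3))
  names(M_arr) <- labels
  free <- coordinate_names(model)
  for (f in seq_len(nf)) {
    fk <- .fk_core(model, stats::setNames(q_traj[f, ], free))
    for (s in seg_names) {
      R_arr[[s]][, , f] <- fk$frames[[s]]$R
      O_arr[[s]][f, ] <- fk$frames[[s]]$origin
    }
    for (l in rownames(fk$markers)) M_arr[[l]][f, ] <- fk$markers[l, ]
  }
  list(R = R_arr, origin = O_arr, markers = M_arr)
}
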
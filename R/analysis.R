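# Trajectory statistics: contacts, binding-frequency profiles, dissociation
# times, dimer angles, RMSF and size metrics.

#' Count contacts between two bead selections in one frame
#'
#' A contact is any bead pair (one from each selection) within the cutoff;
#' the reference cutoff is 0.65 nm.
#'
#' @param frame n x 3 coordinate matrix
#' @param sel_a,sel_b disjoint integer bead id vectors
#' @param cutoff_nm contact cutoff in nanometers
#' @return list with `count` and a two-column `pairs` matrix of bead ids
#' @export
contacts <- function(frame, sel_a, sel_b, cutoff_nm = 0.65) {
  if (!length(sel_a) || !length(sel_b)) stop("empty selection")
  if (length(intersect(sel_a, sel_b))) stop("selections must be disjoint")
  d <- cross_dist(frame[sel_a, , drop = FALSE], frame[sel_b, , drop = FALSE])
  hit <- which(d <= cutoff_nm * 10, arr.ind = TRUE)
  list(count = nrow(hit),
       pairs = cbind(a = sel_a[hit[, 1]], b = sel_b[hit[, 2]]))
}

#' Per-residue nanoplastic binding frequency
#'
#' For each dimer residue, the fraction of sampled (frame, replica) pairs,
#' pooled over replicas, in which any bead of the residue is within the
#' cutoff of any plastic bead.  The sampling window is the final
#' `window_fraction` of each trajectory (the reference protocol samples
#' the last 20 ns of 50 ns runs, i.e. 0.4).
#'
#' @param campaign a `binding_campaign`, or a list of
#'   `list(system, trajectory)` entries
#' @param window_fraction fraction of trailing frames sampled, in (0, 1]
#' @param cutoff_nm contact cutoff (nm)
#' @return class `binding_profile`: data.frame with `residue`, `domain`,
#'   `frequency` plus window metadata attributes
#' @export
binding_frequency <- function(campaign, window_fraction = 0.4,
                              cutoff_nm = 0.65) {
  stopifnot(window_fraction > 0, window_fraction <= 1)
  reps <- if (inherits(campaign, "binding_campaign")) campaign$replicas
          else campaign
  sys0 <- reps[[1]]$system
  din <- bead_ids(sys0, entity = "dimer")
  key <- paste(sys0$beads$domain[din], sys0$beads$residue[din])
  ukey <- unique(key)
  n_hit <- setNames(numeric(length(ukey)), ukey)
  n_tot <- 0L
  for (rep in reps) {
    tr <- rep$trajectory
    sys <- rep$system
    if (!length(sys$plastic_ids)) stop("campaign has no plastic beads")
    nf <- length(tr$frames)
    first <- nf - max(1L, floor(window_fraction * nf)) + 1L
    if (first > nf) stop("no frames in the sampling window")
    for (fidx in first:nf) {
      fr <- tr$frames[[fidx]]
      d <- cross_dist(fr[din, , drop = FALSE],
                      fr[sys$plastic_ids, , drop = FALSE])
      close_bead <- apply(d <= cutoff_nm * 10, 1, any)
      hit_res <- unique(key[close_bead])
      n_hit[hit_res] <- n_hit[hit_res] + 1
      n_tot <- n_tot + 1L
    }
  }
  parts <- strsplit(ukey, " ")
  out <- data.frame(domain = vapply(parts, `[`, "", 1),
                    residue = as.integer(vapply(parts, `[`, "", 2)),
                    frequency = as.numeric(n_hit) / n_tot)
  out <- out[order(out$domain, out$residue), ]
  rownames(out) <- NULL
  structure(out, class = c("binding_profile", "data.frame"),
            window_fraction = window_fraction, cutoff_nm = cutoff_nm,
            n_replicas = length(reps), n_samples = n_tot)
}

#' First dissociation time of a dimer
#'
#' The earliest frame time at which the contact count between the two
#' selections is zero; censored at the trajectory end (or the supplied
#' campaign duration) if contact is never lost.  A transient zero counts:
#' there is no rebinding grace window by default.
#'
#' @param trajectory a `dmd_trajectory` (frames time-ordered)
#' @param sel_a,sel_b bead selections of the two domains
#' @param cutoff_nm contact cutoff (nm)
#' @param duration_ns censoring duration; defaults to the last frame time
#' @param force_pN,replica,seed metadata carried into the record
#' @return one-row data.frame (force_pN, replica, seed, time_ns, censored)
#' @export
first_dissociation <- function(trajectory, sel_a, sel_b, cutoff_nm = 0.65,
                               duration_ns = NULL, force_pN = NA_real_,
                               replica = NA_integer_, seed = NA_integer_) {
  cc <- vapply(trajectory$frames, function(fr)
    contacts(fr, sel_a, sel_b, cutoff_nm)$count, 0L)
  hit <- which(cc == 0L)
  if (is.null(duration_ns)) duration_ns <- max(trajectory$times)
  if (length(hit))
    data.frame(force_pN = force_pN, replica = replica, seed = seed,
               time_ns = trajectory$times[hit[1]], censored = FALSE)
  else
    data.frame(force_pN = force_pN, replica = replica, seed = seed,
               time_ns = duration_ns, censored = TRUE)
}

#' Summarize dissociation records by force
#'
#' Censored replicas carry the campaign duration as a lower bound; means
#' are reported both over all records (`mean_ns`, a lower bound when any
#' record is censored) and over the uncensored subset (`mean_observed_ns`).
#' Quartiles use linear interpolation (R quantile type 7).
#'
#' @param records data.frame as produced by [pulling_campaign()] /
#'   [first_dissociation()]
#' @return data.frame, one row per force
#' @export
dissociation_summary <- function(records) {
  stopifnot(nrow(records) >= 1)
  out <- do.call(rbind, lapply(split(records, records$force_pN), function(g) {
    q <- quantile(g$time_ns, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(force_pN = g$force_pN[1], n = nrow(g),
               n_censored = sum(g$censored),
               all_censored = all(g$censored),
               mean_ns = mean(g$time_ns),
               mean_observed_ns = if (any(!g$censored))
                 mean(g$time_ns[!g$censored]) else NA_real_,
               q25_ns = q[1], median_ns = q[2], q75_ns = q[3],
               min_ns = min(g$time_ns), max_ns = max(g$time_ns))
  }))
  rownames(out) <- NULL
  out[order(out$force_pN), ]
}

#' EC1 dimer angle
#'
#' The angle between the residue-vector of domain A and the same vector of
#' domain B: for the s-dimer definition the vector runs from residue 88 to
#' residue 98 of each domain, for the x-dimer definition from 92 to 99
#' (remappable for synthetic dimers via the model's `angle_map`).  Computed
#' from the normalized dot product, in degrees within [0, 180].
#'
#' @param frame n x 3 coordinate matrix (or a `dmd_trajectory`, in which
#'   case a per-frame data.frame is returned)
#' @param model a `cadherin_model` or `dmd_system`
#' @param definition `"s"` or `"x"`
#' @param residue_map optional length-2 residue index vector overriding the
#'   model's mapping
#' @return angle in degrees, or data.frame (time_ns, angle_deg, definition)
#' @export
dimer_angle <- function(frame, model, definition = c("s", "x"),
                        residue_map = NULL) {
  definition <- match.arg(definition)
  dm <- if (inherits(model, "dmd_system")) model$dimer else model
  rmap <- if (is.null(residue_map)) dm$angle_map[[definition]] else residue_map
  stopifnot(length(rmap) == 2)
  if (inherits(frame, "dmd_trajectory")) {
    ang <- vapply(frame$frames, dimer_angle, 0, model = model,
                  definition = definition, residue_map = residue_map)
    return(data.frame(time_ns = frame$times, angle_deg = ang,
                      definition = definition))
  }
  vec <- function(dom) {
    ia <- bead_ids(model, domain = dom, role = "backbone",
                   residues = rmap[1])
    ib <- bead_ids(model, domain = dom, role = "backbone",
                   residues = rmap[2])
    if (length(ia) != 1 || length(ib) != 1)
      stop("angle residues ", rmap[1], "/", rmap[2],
           " not resolvable in domain ", dom)
    v <- frame[ib, ] - frame[ia, ]
    nv <- sqrt(sum(v^2))
    if (nv == 0) stop("zero-length dimer-angle vector")
    v / nv
  }
  doms <- dm$domains
  d <- sum(vec(doms[1]) * vec(doms[2]))
  acos(max(-1, min(1, d))) * 180 / pi
}

#' Root mean square fluctuation per bead
#'
#' RMSF of each selected bead about its time-mean position over the frames
#' within `window_ns`.  No superposition is applied: the intended use has
#' one domain immobilized, which fixes the reference frame.
#'
#' @param trajectory a `dmd_trajectory`
#' @param ids bead ids
#' @param window_ns length-2 time window (ns); default the whole trajectory
#' @return named numeric vector of RMSF values (Angstrom)
#' @export
rmsf <- function(trajectory, ids, window_ns = NULL) {
  tt <- trajectory$times
  if (is.null(window_ns)) window_ns <- range(tt)
  keep <- which(tt >= window_ns[1] & tt <= window_ns[2])
  if (length(keep) < 2) stop("fewer than 2 frames in the RMSF window")
  arr <- vapply(trajectory$frames[keep],
                function(fr) fr[ids, , drop = FALSE],
                matrix(0, length(ids), 3))
  mean_pos <- apply(arr, c(1, 2), mean)
  dev2 <- sweep(arr, c(1, 2), mean_pos)^2
  out <- sqrt(apply(dev2, 1, mean) * 3)  # mean over frames & coords, x3
  setNames(out, ids)
}

#' Radius of gyration and effective diameter
#'
#' `gyration_radius` is the mass-weighted radius of gyration of a frame
#' (or selection).  `effective_diameter` converts the window-averaged Rg
#' to a sphere diameter by the uniform-sphere convention
#' `D = 2 * sqrt(5/3) * Rg`.
#'
#' @param frame n x 3 coordinate matrix
#' @param masses per-bead masses (Da); equal masses if omitted
#' @param ids optional bead selection
#' @return Rg in Angstrom
#' @export
gyration_radius <- function(frame, masses = NULL, ids = NULL) {
  if (!is.null(ids)) {
    frame <- frame[ids, , drop = FALSE]
    if (!is.null(masses) && length(masses) > nrow(frame))
      masses <- masses[ids]
  }
  n <- nrow(frame)
  if (!n) stop("empty selection")
  if (is.null(masses)) masses <- rep(1, n)
  com <- colSums(frame * masses) / sum(masses)
  sq <- sweep(frame, 2, com)^2
  sqrt(sum(rowSums(sq) * masses) / sum(masses))
}

#' @rdname gyration_radius
#' @param x a `collapse_run`, a `dmd_trajectory`, or a numeric vector of
#'   per-frame Rg values
#' @param window_fraction trailing fraction of frames averaged
#' @export
effective_diameter <- function(x, masses = NULL, ids = NULL,
                               window_fraction = 0.25) {
  rg <- if (inherits(x, "collapse_run")) x$rg
        else if (inherits(x, "dmd_trajectory"))
          vapply(x$frames, gyration_radius, 0, masses = masses, ids = ids)
        else as.numeric(x)
  nf <- length(rg)
  first <- nf - max(1L, floor(window_fraction * nf)) + 1L
  2 * sqrt(5 / 3) * mean(rg[first:nf])
}
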
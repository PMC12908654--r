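#' Geometric hydrogen-bond criterion
#'
#' Default: donor-acceptor distance <= 0.35 nm and H-D-A angle (vertex at
#' the donor) <= 30 degrees. The angle vertex is configurable because the
#' criterion is sometimes stated with the vertex at the hydrogen
#' (D-H-A >= 150 style conventions differ); the donor-vertex form is the
#' default here.
#'
#' @param max_da_nm Maximum donor-acceptor distance, nm.
#' @param max_angle_deg Maximum angle, degrees.
#' @param angle_vertex `"donor"` (H-D-A, default) or `"hydrogen"` (D-H-A,
#'   where the bond requires the angle's *deviation from linearity*
#'   `180 - angle(D,H,A)` to be within `max_angle_deg`).
#' @return A `cw_hbond_criterion`.
#' @export
hbond_criterion <- function(max_da_nm = 0.35, max_angle_deg = 30,
                            angle_vertex = c("donor", "hydrogen")) {
  if (max_da_nm <= 0) stop("distance cutoff must be > 0")
  if (max_angle_deg <= 0 || max_angle_deg > 180) stop("angle must be in (0, 180]")
  structure(list(max_da_nm = max_da_nm, max_angle_deg = max_angle_deg,
                 angle_vertex = match.arg(angle_vertex)),
            class = "cw_hbond_criterion")
}

#' Detect hydrogen bonds in one frame
#'
#' A (donor, hydrogen, acceptor) triple is a bond iff the minimum-image
#' D-A distance and the criterion angle both pass. Every qualifying triple
#' is reported exactly once; self pairs (D == A) are excluded. A donor
#' without attached hydrogens is an error.
#'
#' @param coords Frame positions, n x 3 (nm).
#' @param top A `cw_topology` with donor/acceptor flags and donor
#'   hydrogens assigned.
#' @param box Box edges, nm.
#' @param criterion A `cw_hbond_criterion`.
#' @param donors,acceptors Optional index vectors restricting the search
#'   (default: all flagged donors/acceptors).
#' @return Data.frame with columns `donor`, `hydrogen`, `acceptor`.
#' @export
detect_hbonds <- function(coords, top, box, criterion = hbond_criterion(),
                          donors = NULL, acceptors = NULL) {
  a <- top$atoms
  if (is.null(donors)) donors <- which(a$is_donor)
  if (is.null(acceptors)) acceptors <- which(a$is_acceptor)
  if (!length(donors) || !length(acceptors))
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0)))
  missing_h <- setdiff(as.character(donors), names(top$donor_hydrogens))
  if (length(missing_h))
    stop("donor atom(s) without attached hydrogens: ",
         paste(missing_h, collapse = ", "))
  dmat <- min_image_dist(coords[donors, , drop = FALSE],
                         coords[acceptors, , drop = FALSE], box)
  cand <- which(dmat <= criterion$max_da_nm, arr.ind = TRUE)
  res <- list()
  for (i in seq_len(nrow(cand))) {
    d <- donors[cand[i, 1]]
    acc <- acceptors[cand[i, 2]]
    if (d == acc) next
    dv <- min_image(coords[d, ], coords[acc, ], box)
    for (h in top$donor_hydrogens[[as.character(d)]]) {
      hv <- min_image(coords[d, ], coords[h, ], box)
      ang <- if (criterion$angle_vertex == "donor") {
        vertex_angle(coords[d, ] + hv, coords[d, ], coords[d, ] + dv)
      } else {
        180 - vertex_angle(coords[d, ], coords[d, ] + hv, coords[d, ] + dv)
      }
      if (ang <= criterion$max_angle_deg)
        res[[length(res) + 1L]] <- c(d, h, acc)
    }
  }
  if (!length(res))
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0)))
  out <- as.data.frame(do.call(rbind, res))
  names(out) <- c("donor", "hydrogen", "acceptor")
  out
}

#' Per-frame hydrogen-bond counts between two groups
#'
#' Counts bonds whose donor is in one group and acceptor in the other
#' (both directions). The argument order is immaterial.
#'
#' @param traj A `cw_trajectory`.
#' @param group_a,group_b Selection strings or index vectors (non-empty).
#' @param criterion A `cw_hbond_criterion`.
#' @return A `cw_hbond_series`: data.frame `frame`, `time_ps`, `count`,
#'   with attribute `mean`.
#' @export
hbond_count_series <- function(traj, group_a, group_b,
                               criterion = hbond_criterion()) {
  ia <- resolve_selection(traj$topology, group_a)
  ib <- resolve_selection(traj$topology, group_b)
  if (!length(ia) || !length(ib)) stop("empty group")
  a <- traj$topology$atoms
  counts <- integer(n_frames(traj))
  for (f in seq_len(n_frames(traj))) {
    co <- frame_coords(traj, f)
    ab <- detect_hbonds(co, traj$topology, traj$box[f, ], criterion,
                        donors = intersect(which(a$is_donor), ia),
                        acceptors = intersect(which(a$is_acceptor), ib))
    ba <- detect_hbonds(co, traj$topology, traj$box[f, ], criterion,
                        donors = intersect(which(a$is_donor), ib),
                        acceptors = intersect(which(a$is_acceptor), ia))
    # a triple counted in both directions (groups overlapping) is one bond
    key <- unique(rbind(ab, ba))
    counts[f] <- nrow(key)
  }
  out <- data.frame(frame = seq_len(n_frames(traj)), time_ps = traj$times,
                    count = counts)
  class(out) <- c("cw_hbond_series", "data.frame")
  attr(out, "mean") <- mean(counts)
  out
}

#' @export
print.cw_hbond_series <- function(x, ...) {
  cat(sprintf("<cw_hbond_series> %d frames, mean %.3f bonds/frame\n",
              nrow(x), attr(x, "mean")))
  invisible(x)
}

#' Radial distribution function g(r)
#'
#' Histogram of minimum-image reference-target distances, normalised by
#' the ideal-gas shell expectation at the target's mean density in the
#' full box (bulk convention): for uncorrelated points g(r) = 1. The
#' reference is either the per-frame centroid of its selection (default,
#' the convention for a residue reference) or every reference atom.
#'
#' @param traj A `cw_trajectory`.
#' @param reference,target Selection strings or index vectors.
#' @param r_max Maximum distance, nm; must not exceed half the shortest
#'   box edge (minimum-image validity).
#' @param bin Bin width, nm.
#' @param ref_mode `"centroid"` or `"atoms"`.
#' @return A `cw_rdf`: data.frame `r_nm`, `g`.
#' @export
rdf <- function(traj, reference, target, r_max = NULL, bin = 0.02,
                ref_mode = c("centroid", "atoms")) {
  ref_mode <- match.arg(ref_mode)
  iref <- resolve_selection(traj$topology, reference)
  itar <- resolve_selection(traj$topology, target)
  if (!length(iref) || !length(itar)) stop("empty reference or target selection")
  half_min <- min(traj$box) / 2
  if (is.null(r_max)) r_max <- half_min
  if (r_max > half_min + 1e-9)
    stop("r_max exceeds half the shortest box edge (", signif(half_min, 4), " nm)")
  nb <- ceiling(r_max / bin)
  counts <- numeric(nb)
  n_ref_tot <- 0
  rho_sum <- 0
  for (f in seq_len(n_frames(traj))) {
    co <- frame_coords(traj, f)
    refp <- if (ref_mode == "centroid") {
      matrix(colMeans(rbind(co[iref, , drop = FALSE])), 1, 3)
    } else co[iref, , drop = FALSE]
    d <- min_image_dist(refp, co[itar, , drop = FALSE], traj$box[f, ])
    d <- d[d > 1e-9 & d <= r_max]
    counts <- counts + tabulate(pmin(nb, floor(d / bin) + 1L), nbins = nb)
    n_ref_tot <- n_ref_tot + nrow(refp)
    rho_sum <- rho_sum + length(itar) / prod(traj$box[f, ])
  }
  rho <- rho_sum / n_frames(traj)
  r_lo <- (seq_len(nb) - 1L) * bin
  shell <- 4 / 3 * pi * ((r_lo + bin)^3 - r_lo^3)
  g <- counts / (n_ref_tot * rho * shell)
  out <- data.frame(r_nm = r_lo + bin / 2, g = g)
  class(out) <- c("cw_rdf", "data.frame")
  attr(out, "rho_nm3") <- rho
  out
}

# Lorentz-Berthelot combination: arithmetic sigma, geometric epsilon.
lb_combine <- function(eps_i, sig_i, eps_j, sig_j) {
  list(eps = sqrt(outer(eps_i, eps_j)),
       sig = outer(sig_i, sig_j, function(a, b) (a + b) / 2))
}

#' Coulomb interaction energy between two atom groups
#'
#' Bare pairwise sum `f sum q_i q_j / r_ij` over all (i in A, j in B)
#' pairs with minimum-image distances and the electric conversion factor
#' `f = 138.935458 kJ mol^-1 nm e^-2`. Groups must be disjoint (a shared
#' atom would be a self interaction). A plain (untapered) cutoff may be
#' given; the default is the full sum, since the analysis equations are
#' bare sums and mesh electrostatics belong to the simulation engine, not
#' the analysis.
#'
#' @param coords Frame positions, n x 3 (nm).
#' @param top A `cw_topology` with charges assigned.
#' @param box Box edges, nm.
#' @param group_a,group_b Selections (strings or index vectors), disjoint.
#' @param cutoff Optional plain distance cutoff, nm.
#' @return Energy in kJ/mol.
#' @export
coulomb_energy <- function(coords, top, box, group_a, group_b, cutoff = NULL) {
  ia <- resolve_selection(top, group_a)
  ib <- resolve_selection(top, group_b)
  if (length(intersect(ia, ib)))
    stop("groups overlap: self-interaction is undefined")
  q <- top$atoms$charge
  if (anyNA(q[c(ia, ib)])) stop("charges not assigned for all group atoms")
  d <- min_image_dist(coords[ia, , drop = FALSE], coords[ib, , drop = FALSE], box)
  qq <- outer(q[ia], q[ib])
  e <- cw_constants$coulomb_kj_nm_e2 * qq / d
  if (!is.null(cutoff)) e[d > cutoff] <- 0
  sum(e)
}

#' Lennard-Jones interaction energy between two atom groups
#'
#' `sum 4 eps_ij [ (sig_ij/r)^12 - (sig_ij/r)^6 ]` with Lorentz-Berthelot
#' combination (arithmetic sigma, geometric epsilon); equivalent to the
#' A/B coefficient form with `A = 4 eps sig^12`, `B = 4 eps sig^6`.
#'
#' @inheritParams coulomb_energy
#' @return Energy in kJ/mol.
#' @export
lj_energy <- function(coords, top, box, group_a, group_b, cutoff = NULL) {
  ia <- resolve_selection(top, group_a)
  ib <- resolve_selection(top, group_b)
  if (length(intersect(ia, ib)))
    stop("groups overlap: self-interaction is undefined")
  eps <- top$atoms$eps; sig <- top$atoms$sigma
  bad <- c(ia, ib)[is.na(eps[c(ia, ib)]) | is.na(sig[c(ia, ib)])]
  if (length(bad))
    stop("Lennard-Jones parameters missing for atom(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  d <- min_image_dist(coords[ia, , drop = FALSE], coords[ib, , drop = FALSE], box)
  comb <- lb_combine(eps[ia], sig[ia], eps[ib], sig[ib])
  sr6 <- (comb$sig / d)^6
  e <- 4 * comb$eps * (sr6^2 - sr6)
  e[comb$eps == 0] <- 0
  if (!is.null(cutoff)) e[d > cutoff] <- 0
  sum(e)
}

#' Time-averaged residue-water interaction energies
#'
#' Per-residue mean Coulomb and Lennard-Jones energy against the water
#' group, with `total = coulomb + lennard_jones` per residue; totals are
#' additive over residues.
#'
#' @param traj A `cw_trajectory` with parameters assigned.
#' @param residues Integer vector of residue ids, or a named list of
#'   selections (names become row labels).
#' @param waters Selection for the water group (default `"water"`).
#' @param cutoff Optional plain cutoff, nm (default: full sum).
#' @return A `cw_energy_table`: data.frame `residue`, `coulomb_kJmol`,
#'   `lj_kJmol`, `total_kJmol`.
#' @export
interaction_energy_per_residue <- function(traj, residues, waters = "water",
                                           cutoff = NULL) {
  if (!length(residues)) stop("residue list is empty")
  top <- traj$topology
  iw <- resolve_selection(top, waters)
  sels <- if (is.list(residues)) {
    lapply(residues, resolve_selection, top = top)
  } else {
    stats::setNames(lapply(residues, function(r) which(top$atoms$resid == r)),
                    paste0(top$atoms$resname[match(residues, top$atoms$resid)],
                           residues))
  }
  nf <- n_frames(traj)
  rows <- lapply(names(sels), function(nm) {
    ir <- setdiff(sels[[nm]], iw)
    ec <- el <- 0
    for (f in seq_len(nf)) {
      co <- frame_coords(traj, f)
      ec <- ec + coulomb_energy(co, top, traj$box[f, ], ir, iw, cutoff)
      el <- el + lj_energy(co, top, traj$box[f, ], ir, iw, cutoff)
    }
    data.frame(residue = nm, coulomb_kJmol = ec / nf, lj_kJmol = el / nf)
  })
  out <- do.call(rbind, rows)
  out$total_kJmol <- out$coulomb_kJmol + out$lj_kJmol
  class(out) <- c("cw_energy_table", "data.frame")
  out
}

#' Field-minus-baseline interaction-energy differences
#'
#' `dE = E(field) - E(baseline)` per residue: positive values mean the
#' field destabilised the residue-water interaction. Topologies must
#' match atom-for-atom.
#'
#' @param traj_field,traj_baseline Trajectories with identical topologies.
#' @inheritParams interaction_energy_per_residue
#' @return Data.frame `residue`, `d_coulomb_kJmol`, `d_lj_kJmol`,
#'   `d_total_kJmol`.
#' @export
delta_energy <- function(traj_field, traj_baseline, residues,
                         waters = "water", cutoff = NULL) {
  ta <- traj_field$topology$atoms; tb <- traj_baseline$topology$atoms
  if (nrow(ta) != nrow(tb) || !all(ta$name == tb$name & ta$resid == tb$resid))
    stop("topology mismatch between the two runs")
  ef <- interaction_energy_per_residue(traj_field, residues, waters, cutoff)
  eb <- interaction_energy_per_residue(traj_baseline, residues, waters, cutoff)
  data.frame(residue = ef$residue,
             d_coulomb_kJmol = ef$coulomb_kJmol - eb$coulomb_kJmol,
             d_lj_kJmol = ef$lj_kJmol - eb$lj_kJmol,
             d_total_kJmol = ef$total_kJmol - eb$total_kJmol)
}

#' Mean number of water oxygens near each residue
#'
#' Time-averaged count of water oxygens within `cutoff` nm (minimum
#' image) of *any* atom of the residue.
#'
#' @param traj A `cw_trajectory`.
#' @param residues Residue ids or named list of selections.
#' @param cutoff Distance cutoff, nm (default 0.5).
#' @return Data.frame `residue`, `mean_count`.
#' @export
local_water_count <- function(traj, residues, cutoff = 0.5) {
  top <- traj$topology
  wt <- top$waters
  sels <- if (is.list(residues)) {
    lapply(residues, resolve_selection, top = top)
  } else {
    stats::setNames(lapply(residues, function(r) which(top$atoms$resid == r)),
                    paste0(top$atoms$resname[match(residues, top$atoms$resid)],
                           residues))
  }
  nf <- n_frames(traj)
  rows <- lapply(names(sels), function(nm) {
    ir <- sels[[nm]]
    tot <- 0
    if (cutoff > 0) for (f in seq_len(nf)) {
      co <- frame_coords(traj, f)
      d <- min_image_dist(co[wt[, 1], , drop = FALSE],
                          co[ir, , drop = FALSE], traj$box[f, ])
      tot <- tot + sum(apply(d <= cutoff, 1, any))
    }
    data.frame(residue = nm, mean_count = tot / nf)
  })
  do.call(rbind, rows)
}
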
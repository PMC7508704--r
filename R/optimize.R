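## Model refinement: a geometric energy (soft-sphere clash repulsion plus
## harmonic connectivity and flanking-pair restraints), rigid-body
## gradient-descent clash relief, simulated annealing Monte Carlo over
## moveable elements derived from the stem tree, and k-medoid clustering of
## the sampled ensemble on pairwise RMSD.

#' Energy parameters
#'
#' `contact` is the soft-sphere contact distance between non-bonded heavy
#' atoms; atom pairs closer than it are penalized quadratically with force
#' constant `k_clash`.  `k_restraint` is the force constant of the harmonic
#' restraints holding chain connectivity across SSE junctions and the
#' flanking base pairs; each restraint is flat within `deadzone` of its
#' assembled target distance.
#'
#' @param contact angstroms; default 2.8.
#' @param k_clash score units per square angstrom; default 10.
#' @param k_restraint score units per square angstrom; default 10.
#' @param deadzone angstroms; default 0.5.
#' @return named list.
#' @export
energy_params <- function(contact = 2.8, k_clash = 10, k_restraint = 10,
                          deadzone = 0.5) {
  list(contact = contact, k_clash = k_clash, k_restraint = k_restraint,
       deadzone = deadzone)
}

## Restraint topology, built once per assembled model: atom-row indices of
## the O3'-P junction bonds and of the glycosidic nitrogens of every
## flanking pair, with their assembled distances as targets.
build_topology <- function(result, params = energy_params()) {
  at <- result$atoms
  n <- length(result$seq)
  xyz <- result_xyz(result)
  owner <- result$owner
  row_of <- function(r, name) {
    w <- which(at$res == r & at$atom == name)
    if (length(w)) w[1] else NA_integer_
  }
  bonds <- NULL
  for (i in seq_len(n - 1)) {
    if (owner[i] == owner[i + 1]) next
    ai <- row_of(i, "O3'"); aj <- row_of(i + 1, "P")
    if (is.na(ai) || is.na(aj)) next
    bonds <- rbind(bonds, c(ai, aj))
  }
  fl <- NULL
  seen <- character(0)
  for (rec in result$records) {
    fp <- rec$flanking_pairs
    for (k in seq_len(nrow(fp))) {
      key <- paste(fp[k, 1], fp[k, 2])
      if (key %in% seen) next
      seen <- c(seen, key)
      ai <- row_of(fp[k, 1], GLYCOSIDIC_N[[result$seq[fp[k, 1]]]])
      aj <- row_of(fp[k, 2], GLYCOSIDIC_N[[result$seq[fp[k, 2]]]])
      if (is.na(ai) || is.na(aj)) next
      fl <- rbind(fl, c(ai, aj))
    }
  }
  pair_target <- function(m) {
    if (is.null(m)) return(data.frame(ai = integer(), aj = integer(),
                                      target = numeric()))
    d <- sqrt(rowSums((xyz[m[, 1], , drop = FALSE] -
                       xyz[m[, 2], , drop = FALSE])^2))
    data.frame(ai = m[, 1], aj = m[, 2], target = d)
  }
  list(res = at$res, owner_atom = owner[at$res],
       bonds = pair_target(bonds), flank = pair_target(fl))
}

restraint_energy_rows <- function(xyz, tab, params, rows = seq_len(nrow(tab))) {
  if (length(rows) == 0) return(0)
  d <- sqrt(rowSums((xyz[tab$ai[rows], , drop = FALSE] -
                     xyz[tab$aj[rows], , drop = FALSE])^2))
  pen <- pmax(0, abs(d - tab$target[rows]) - params$deadzone)
  params$k_restraint * sum(pen^2)
}

## Clash energy between the atoms of residue set `mres` and all others
## (owner-exclusion: pairs within one SSE record or between sequence-adjacent
## residues are not counted).
cross_clash_energy <- function(xyz, topo, params, mres, detail = FALSE) {
  ia <- which(topo$res %in% mres)
  ib <- which(!(topo$res %in% mres))
  if (length(ia) == 0 || length(ib) == 0)
    return(if (detail) list(E = 0) else 0)
  A <- xyz[ia, , drop = FALSE]; B <- xyz[ib, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * (A %*% t(B))
  d <- sqrt(pmax(d2, 0))
  excl <- outer(topo$owner_atom[ia], topo$owner_atom[ib], "==") |
          abs(outer(topo$res[ia], topo$res[ib], "-")) <= 1
  hit <- which(d < params$contact & !excl, arr.ind = TRUE)
  if (nrow(hit) == 0) return(if (detail) list(E = 0) else 0)
  dd <- d[hit]
  E <- params$k_clash * sum((params$contact - dd)^2)
  if (!detail) return(E)
  list(E = E, ia = ia[hit[, 1]], ib = ib[hit[, 2]], d = dd)
}

cross_restraint_rows <- function(topo, mres) {
  pick <- function(tab) {
    inm_i <- topo$res[tab$ai] %in% mres
    inm_j <- topo$res[tab$aj] %in% mres
    which(xor(inm_i, inm_j))
  }
  list(bonds = pick(topo$bonds), flank = pick(topo$flank))
}

element_cross_energy <- function(xyz, topo, params, mres) {
  rows <- cross_restraint_rows(topo, mres)
  cross_clash_energy(xyz, topo, params, mres) +
    restraint_energy_rows(xyz, topo$bonds, params, rows$bonds) +
    restraint_energy_rows(xyz, topo$flank, params, rows$flank)
}

#' Geometric energy of an assembled model
#'
#' Soft-sphere repulsion between heavy atoms of different SSE records
#' (sequence-adjacent residues excluded) plus harmonic connectivity
#' restraints at SSE junctions and harmonic restraints holding the flanking
#' base pairs, both flat within a deadzone of their assembled distances.
#'
#' @param result `assembly_result`.
#' @param params [energy_params()].
#' @param scorer optional replacement scoring function taking
#'   `(xyz, result)` and returning a scalar; when given, it is used instead
#'   of the built-in energy.
#' @return scalar energy (score units).
#' @export
assembly_energy <- function(result, params = energy_params(),
                            scorer = NULL) {
  xyz <- result_xyz(result)
  if (!is.null(scorer)) return(scorer(xyz, result))
  topo <- result$topology
  if (is.null(topo)) topo <- build_topology(result, params)
  E <- restraint_energy_rows(xyz, topo$bonds, params) +
       restraint_energy_rows(xyz, topo$flank, params)
  owners <- unique(topo$owner_atom)
  ## sum cross-record clash energy; each unordered record pair counted once
  for (ow in owners) {
    mres <- which(result$owner == ow)
    E <- E + cross_clash_energy(xyz, topo, params, mres) / 2
  }
  E
}

## Count residual clash contacts (atom pairs between different records,
## non-adjacent residues, closer than the contact distance).
count_clashes <- function(result, params = energy_params()) {
  xyz <- result_xyz(result)
  topo <- result$topology
  total <- 0
  for (ow in unique(topo$owner_atom)) {
    mres <- which(result$owner == ow)
    det <- cross_clash_energy(xyz, topo, params, mres, detail = TRUE)
    if (det$E > 0) total <- total + length(det$d)
  }
  total / 2
}

#' Relieve steric clashes by rigid-body gradient descent
#'
#' Treats each SSE record's owned residues as a rigid group and performs
#' backtracking steepest descent (translation along the net inter-group
#' force, small rotation along the net torque) on the assembly energy.
#' The energy is non-increasing over accepted steps; iteration stops at a
#' force-norm tolerance, when no step improves the energy, or at
#' `max_iter`.
#'
#' @param result `assembly_result`.
#' @param params [energy_params()].
#' @param max_iter maximum sweeps over the elements.
#' @param tol force-norm convergence tolerance.
#' @return the minimized `assembly_result` (energy updated).
#' @export
minimize_clashes <- function(result, params = energy_params(),
                             max_iter = 200, tol = 1e-3) {
  xyz <- result_xyz(result)
  if (any(!is.finite(xyz))) stop("non-finite coordinates")
  topo <- result$topology
  if (is.null(topo)) {
    topo <- build_topology(result, params)
    result$topology <- topo
  }
  elements <- split(seq_along(result$owner), result$owner)
  trans_steps <- c(0.4, 0.2, 0.1, 0.05, 0.02)
  rot_steps <- c(0.1, 0.05, 0.02, 0.01)
  for (iter in seq_len(max_iter)) {
    improved <- FALSE
    max_force <- 0
    for (el in elements) {
      ia <- which(topo$res %in% el)
      det <- cross_clash_energy(xyz, topo, params, el, detail = TRUE)
      F <- c(0, 0, 0); cm <- colMeans(xyz[ia, , drop = FALSE])
      tau <- c(0, 0, 0)
      if (det$E > 0) {
        for (q in seq_along(det$d)) {
          dvec <- xyz[det$ia[q], ] - xyz[det$ib[q], ]
          f <- 2 * params$k_clash * (params$contact - det$d[q]) *
               dvec / max(det$d[q], 1e-6)
          F <- F + f
          tau <- tau + cross3(xyz[det$ia[q], ] - cm, f)
        }
      }
      rows <- cross_restraint_rows(topo, el)
      for (tabname in c("bonds", "flank")) {
        tab <- topo[[tabname]]
        for (q in rows[[tabname]]) {
          ai <- tab$ai[q]; aj <- tab$aj[q]
          if (!(topo$res[ai] %in% el)) { tmp <- ai; ai <- aj; aj <- tmp }
          dvec <- xyz[ai, ] - xyz[aj, ]
          d <- vnorm(dvec)
          pen <- abs(d - tab$target[q]) - params$deadzone
          if (pen <= 0) next
          f <- -2 * params$k_restraint * pen * sign(d - tab$target[q]) *
               dvec / max(d, 1e-6)
          F <- F + f
          tau <- tau + cross3(xyz[ai, ] - cm, f)
        }
      }
      fn <- vnorm(F)
      max_force <- max(max_force, fn)
      if (fn < tol && vnorm(tau) < tol) next
      E0 <- element_cross_energy(xyz, topo, params, el)
      ## translation line search
      if (fn >= tol) {
        u <- F / fn
        for (stp in trans_steps) {
          xyz2 <- xyz
          xyz2[ia, ] <- sweep(xyz2[ia, , drop = FALSE], 2, stp * u, "+")
          if (element_cross_energy(xyz2, topo, params, el) < E0 - 1e-10) {
            xyz <- xyz2; improved <- TRUE
            E0 <- element_cross_energy(xyz, topo, params, el)
            break
          }
        }
      }
      ## rotation line search about the centroid
      tn <- vnorm(tau)
      if (tn >= tol) {
        for (ang in rot_steps) {
          Rm <- rot_axis(tau, ang)
          xyz2 <- xyz
          xyz2[ia, ] <- sweep(sweep(xyz2[ia, , drop = FALSE], 2, cm) %*% Rm,
                              2, cm, "+")
          if (element_cross_energy(xyz2, topo, params, el) < E0 - 1e-10) {
            xyz <- xyz2; improved <- TRUE
            break
          }
        }
      }
    }
    if (!improved || max_force < tol) break
  }
  result <- set_result_xyz(result, xyz)
  result$energy <- assembly_energy(result, params)
  if (!is.finite(result$energy)) stop("non-finite energy after minimization")
  result
}

#' Moveable elements for Monte Carlo refinement
#'
#' Derived from the stem tree: every non-exterior stem together with its
#' distal subtree forms one rigid element (pivot at the P atom of its
#' outermost 5' residue), and every unpaired loop segment forms one element.
#' Elements spanning the entire chain are dropped (moving them cannot change
#' the energy).
#'
#' @param result `assembly_result`.
#' @return list of elements, each `list(residues, pivot_row)`.
#' @export
derive_moveable_elements <- function(result) {
  records <- result$records
  n <- length(result$seq)
  nrec <- length(records)
  shared <- function(a, b)
    length(intersect(records[[a]]$residues, records[[b]]$residues)) >= 2
  is_open <- vapply(records, function(r) r$sse_type == "open_loop",
                    logical(1))
  root <- if (any(is_open)) which(is_open)[1] else 1L
  parent <- rep(NA_integer_, nrec)
  ord <- integer(0)
  visited <- logical(nrec)
  queue <- root; visited[root] <- TRUE
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    ord <- c(ord, cur)
    for (k in seq_len(nrec)) {
      if (!visited[k] && shared(cur, k)) {
        visited[k] <- TRUE
        parent[k] <- cur
        queue <- c(queue, k)
      }
    }
  }
  subtree_res <- function(k) {
    out <- records[[k]]$residues
    for (q in seq_len(nrec)) {
      if (!is.na(parent[q]) && parent[q] == k)
        out <- union(out, subtree_res(q))
    }
    out
  }
  elements <- list()
  add <- function(residues, pivot_res) {
    residues <- sort(residues)
    if (length(residues) == 0 || length(residues) >= n) return()
    at <- result$atoms
    pr <- which(at$res == pivot_res & at$atom == "P")
    if (length(pr) == 0) pr <- which(at$res == pivot_res & at$atom == "C4'")
    for (e in elements)
      if (identical(e$residues, residues)) return()
    elements[[length(elements) + 1]] <<- list(residues = residues,
                                              pivot_row = pr[1])
  }
  for (k in seq_len(nrec)) {
    if (records[[k]]$sse_type == "stem" && k != root)
      add(subtree_res(k), min(records[[k]]$residues))
  }
  for (k in seq_len(nrec)) {
    rec <- records[[k]]
    if (rec$sse_type == "stem") next
    own <- which(result$owner == k)
    for (run in contiguous_runs(own))
      add(seq.int(run[1], run[2]), run[1])
  }
  elements
}

#' Simulated annealing Monte Carlo schedule
#'
#' @param T_start,T_end start and floor temperatures (score units).
#' @param cooling geometric cooling factor applied every `cool_every` steps.
#' @param cool_every steps between cooling events.
#' @param max_trans maximum translation per move, angstroms.
#' @param max_rot_deg maximum rotation per move, degrees.
#' @return named list.
#' @export
samc_schedule <- function(T_start = 5, T_end = 0.1, cooling = 0.98,
                          cool_every = 100, max_trans = 2,
                          max_rot_deg = 10) {
  list(T_start = T_start, T_end = T_end, cooling = cooling,
       cool_every = cool_every, max_trans = max_trans,
       max_rot_deg = max_rot_deg)
}

#' Refine a model by simulated annealing Monte Carlo
#'
#' At each step a randomly chosen moveable element is translated, rotated
#' around its centroid, or rotated around a random axis through its pivot,
#' and the move is accepted by the Metropolis criterion at the current
#' temperature under geometric cooling.  Snapshots are taken every
#' `sample_every` accepted moves; the best-energy structure seen is always
#' part of the returned ensemble.  The trajectory is reproducible for a
#' fixed seed.
#'
#' @param result minimized `assembly_result`.
#' @param n_steps number of proposed moves.
#' @param schedule [samc_schedule()].
#' @param sample_every accepted moves between snapshots.
#' @param seed integer seed.
#' @param params [energy_params()].
#' @param scorer optional scoring function `(xyz, result) -> scalar`
#'   replacing the built-in energy (evaluated on the full structure at each
#'   step).
#' @return list of `assembly_result` snapshots with an `energies` attribute.
#' @export
samc_optimize <- function(result, n_steps = 2000,
                          schedule = samc_schedule(), sample_every = 100,
                          seed = 1, params = energy_params(),
                          scorer = NULL) {
  elements <- derive_moveable_elements(result)
  if (length(elements) == 0) {
    warning("no moveable elements (single rigid SSE); returning the input")
    return(structure(list(result),
                     energies = result$energy))
  }
  topo <- result$topology
  if (is.null(topo)) {
    topo <- build_topology(result, params)
    result$topology <- topo
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  xyz <- result_xyz(result)
  E <- if (is.null(scorer)) assembly_energy(result, params)
       else scorer(xyz, result)
  T <- schedule$T_start
  best_xyz <- xyz; best_E <- E
  snaps <- list(); snap_E <- numeric(0)
  accepted <- 0L
  rand_unit <- function() unitv(stats::rnorm(3))
  for (step in seq_len(n_steps)) {
    el <- elements[[sample.int(length(elements), 1)]]
    ia <- which(topo$res %in% el$residues)
    move <- sample.int(3, 1)
    xyz2 <- xyz
    if (move == 1) {
      delta <- rand_unit() * stats::runif(1, 0, schedule$max_trans)
      xyz2[ia, ] <- sweep(xyz2[ia, , drop = FALSE], 2, delta, "+")
    } else {
      center <- if (move == 2) colMeans(xyz[ia, , drop = FALSE])
                else xyz[el$pivot_row, ]
      ang <- stats::runif(1, -1, 1) * schedule$max_rot_deg * pi / 180
      Rm <- rot_axis(rand_unit(), ang)
      xyz2[ia, ] <- sweep(sweep(xyz2[ia, , drop = FALSE], 2, center) %*% Rm,
                          2, center, "+")
    }
    if (is.null(scorer)) {
      dE <- element_cross_energy(xyz2, topo, params, el$residues) -
            element_cross_energy(xyz, topo, params, el$residues)
    } else {
      dE <- scorer(xyz2, result) - scorer(xyz, result)
    }
    if (dE <= 0 || stats::runif(1) < exp(-dE / max(T, 1e-9))) {
      xyz <- xyz2
      E <- E + dE
      accepted <- accepted + 1L
      if (E < best_E) { best_E <- E; best_xyz <- xyz }
      if (accepted %% sample_every == 0L) {
        snap <- set_result_xyz(result, xyz)
        ## store the exactly recomputed energy, not the incremental sum
        snap$energy <- if (is.null(scorer)) assembly_energy(snap, params)
                       else E
        snaps[[length(snaps) + 1]] <- snap
        snap_E <- c(snap_E, snap$energy)
      }
    }
    if (step %% schedule$cool_every == 0L)
      T <- max(schedule$T_end, T * schedule$cooling)
  }
  if (length(snaps) == 0 || best_E < min(snap_E)) {
    snap <- set_result_xyz(result, best_xyz)
    snap$energy <- if (is.null(scorer)) assembly_energy(snap, params)
                   else best_E
    snaps[[length(snaps) + 1]] <- snap
    snap_E <- c(snap_E, snap$energy)
  }
  attr(snaps, "energies") <- snap_E
  attr(snaps, "acceptance_rate") <- accepted / n_steps
  snaps
}

## Exact k-medoid partition by enumeration (small ensembles), else PAM.
kmedoids_rmsd <- function(D, N) {
  m <- nrow(D)
  if (choose(m, N) <= 20000) {
    sets <- utils::combn(m, N)
    best <- NULL; best_cost <- Inf
    for (k in seq_len(ncol(sets))) {
      med <- sets[, k]
      cost <- sum(apply(D[, med, drop = FALSE], 1, min))
      if (cost < best_cost - 1e-12) { best_cost <- cost; best <- med }
    }
    best
  } else {
    fit <- cluster::pam(D, N, diss = TRUE)
    sort(fit$id.med)
  }
}

#' Cluster an ensemble and return ranked representatives
#'
#' Computes the pairwise RMSD matrix (after per-pair optimal superposition),
#' partitions the ensemble into `N` clusters by k-medoids on that matrix
#' (exact enumeration for small ensembles, PAM otherwise), and returns the
#' cluster medoids ranked by energy ascending.
#'
#' @param ensemble list of `assembly_result` (e.g. from [samc_optimize()]).
#' @param N number of clusters / representatives.
#' @return list of `N` representatives, best first, with a `rank_table`
#'   attribute (rank, energy, RMSD to rank 1).
#' @export
cluster_and_rank <- function(ensemble, N) {
  m <- length(ensemble)
  if (m < N) {
    warning(sprintf("ensemble of %d smaller than N = %d; reducing N", m, N))
    N <- m
  }
  xyzs <- lapply(ensemble, result_xyz)
  D <- matrix(0, m, m)
  for (i in seq_len(m - 1)) {
    for (j in seq.int(i + 1, m)) {
      D[i, j] <- D[j, i] <- superpose(xyzs[[j]], xyzs[[i]])$rmsd
    }
  }
  med <- kmedoids_rmsd(D, N)
  energies <- vapply(ensemble[med], function(r) r$energy, numeric(1))
  ord <- order(energies, med)
  med <- med[ord]
  reps <- ensemble[med]
  tab <- data.frame(rank = seq_len(N),
                    energy = energies[ord],
                    rmsd_to_rank1 = D[med, med[1]])
  attr(reps, "rank_table") <- tab
  attr(reps, "medoids") <- med
  reps
}
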
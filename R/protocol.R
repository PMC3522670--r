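# Stage orchestration: starting-structure generation, pre-assembly
# (symmetry imposition), assembly into a coarse map, GVM re-ranking against
# the fine map, combinatorial recombination of partial solutions, and
# staged refinement with the intermolecular force field.

# ---- structure pool --------------------------------------------------------

#' Construct a structure pool
#'
#' A ranked collection of candidate assemblies sharing one set of component
#' models. Poses are stored per structure; scores and provenance live in a
#' data frame aligned with the structure list.
#'
#' @param models list of \code{coarse_model} (one per component).
#' @param structures list; each element is a list of \code{rigid_pose}, one
#'   per component.
#' @param scores data.frame with one row per structure (created empty when
#'   missing).
#' @return object of class \code{structure_pool}.
#' @export
structure_pool <- function(models, structures, scores = NULL) {
  if (is.null(scores))
    scores <- data.frame(stage = rep("start", length(structures)),
                         stringsAsFactors = FALSE)
  if (nrow(scores) != length(structures))
    stop("scores must have one row per structure")
  structure(list(models = models, structures = structures, scores = scores),
            class = "structure_pool")
}

#' @export
print.structure_pool <- function(x, ...) {
  cat("structure_pool: ", pool_size(x), " structures x ",
      length(x$models), " components\n", sep = "")
  keys <- intersect(c("total", "symmetry", "gvm"), names(x$scores))
  if (length(keys) > 0 && pool_size(x) > 0) {
    for (k in keys)
      cat("  ", k, ": best ", signif(min(x$scores[[k]], na.rm = TRUE), 5),
          ", median ", signif(median(x$scores[[k]], na.rm = TRUE), 5),
          "\n", sep = "")
  }
  invisible(x)
}

#' @rdname structure_pool
#' @param pool \code{structure_pool}.
#' @export
pool_size <- function(pool) length(pool$structures)

#' @rdname structure_pool
#' @param i structure index.
#' @export
pool_assembly <- function(pool, i) {
  assembly(pool$models, pool$structures[[i]])
}

pool_reorder <- function(pool, ord) {
  pool$structures <- pool$structures[ord]
  pool$scores <- pool$scores[ord, , drop = FALSE]
  rownames(pool$scores) <- NULL
  pool
}

pool_truncate <- function(pool, n) {
  n <- min(n, pool_size(pool))
  pool$structures <- pool$structures[seq_len(n)]
  pool$scores <- pool$scores[seq_len(n), , drop = FALSE]
  pool
}

# deterministic per-structure random stream derived from (seed, index)
substream_seed <- function(seed, index) {
  (as.integer(seed %% 100000L) * 20011L + as.integer(index)) %% 2147483563L
}

# ---- stage plan ------------------------------------------------------------

#' Stage plan: pool sizes, iteration budgets and stage weights
#'
#' The \code{"full"} preset encodes the reference full-scale protocol (1e6
#' starts, 5e5 after pre-assembly, 1e5 scored, 1e3 refined); the default
#' \code{"desk"} preset is scaled for interactive use and testing.
#'
#' @param preset \code{"desk"} or \code{"full"}.
#' @param ... overrides of individual fields.
#' @return list of class \code{stage_plan}.
#' @export
stage_plan <- function(preset = c("desk", "full"), ...) {
  preset <- match.arg(preset)
  plan <- if (preset == "full") {
    list(n_starts = 1e6, preassembly_keep = 5e5, scoring_keep = 1e5,
         refine_keep = 1e3, recombine_top = 100,
         preassembly_iter = 100, assembly_iter = 200, refine_iter = 100)
  } else {
    list(n_starts = 2000, preassembly_keep = 1000, scoring_keep = 200,
         refine_keep = 32, recombine_top = 60,
         preassembly_iter = 40, assembly_iter = 60, refine_iter = 60)
  }
  plan <- modifyList(plan, list(...))
  with(plan, stopifnot(n_starts >= preassembly_keep,
                       preassembly_keep >= scoring_keep,
                       scoring_keep >= refine_keep))
  structure(plan, class = "stage_plan")
}

# ---- starting structures ---------------------------------------------------

#' Random starting structures
#'
#' Positions uniform in a box, orientations uniform over rotations;
#' reproducible per seed (per-structure streams are derived from the seed
#' and the structure index).
#'
#' @param models list of \code{coarse_model}.
#' @param n number of structures.
#' @param box list with \code{lo} and \code{hi} corners (Angstrom).
#' @param seed master seed.
#' @return \code{structure_pool}.
#' @export
random_starts <- function(models, n, box, seed = 1) {
  if (n < 1) stop("n must be >= 1")
  if (any(box$hi <= box$lo)) stop("empty box")
  coms <- lapply(models, model_com)
  structures <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(substream_seed(seed, i))
    poses <- lapply(seq_along(models), function(j) {
      R <- random_rotation()
      target <- runif(3, box$lo, box$hi)
      rigid_pose(R, target - as.numeric(R %*% coms[[j]]))
    })
    structures[[i]] <- poses
  }
  structure_pool(models, structures)
}

#' Ring-topology starting structures
#'
#' For each structure and each ring: a shared axial offset Z + U(-z_jitter,
#' z_jitter), a radius U(radius - radius_jitter, radius + radius_jitter), a
#' random phase for the first component with the remaining X-1 evenly
#' spaced on the circle in the xy plane, and a random orientation per
#' component. The reference geometry for the three-ring chaperonin-style
#' system is Z = -64.4 / 0.0 / 71.4 Angstrom with radius 35 +/- 15.
#'
#' @param rings list of ring specs: \code{list(model=, X=, Z=, radius=,
#'   radius_jitter=15, z_jitter=5)}.
#' @param n number of structures.
#' @param seed master seed.
#' @return \code{structure_pool}; components are ordered ring by ring.
#' @export
ring_topology_starts <- function(rings, n, seed = 1) {
  if (n < 1) stop("n must be >= 1")
  for (r in rings) if (r$X < 1) stop("ring subunit count must be >= 1")
  models <- unlist(lapply(rings, function(r)
    replicate(r$X, r$model, simplify = FALSE)), recursive = FALSE)
  coms <- lapply(models, model_com)
  structures <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(substream_seed(seed, i))
    poses <- list()
    ci <- 0L
    for (r in rings) {
      zj <- if (is.null(r$z_jitter)) 5 else r$z_jitter
      rj <- if (is.null(r$radius_jitter)) 15 else r$radius_jitter
      z <- r$Z + runif(1, -zj, zj)
      rad <- runif(1, r$radius - rj, r$radius + rj)
      phase <- runif(1, 0, 2 * pi)
      for (k in seq_len(r$X)) {
        ci <- ci + 1L
        ang <- phase + (k - 1) * 2 * pi / r$X
        target <- c(rad * cos(ang), rad * sin(ang), z)
        R <- random_rotation()
        poses[[ci]] <- rigid_pose(R, target - as.numeric(R %*% coms[[ci]]))
      }
    }
    structures[[i]] <- poses
  }
  structure_pool(models, structures)
}

# ---- stages ----------------------------------------------------------------

#' Pre-assembly stage: impose symmetry on the starting structures
#'
#' Minimizes the symmetry energy per structure with all density and atomic
#' terms off -- orientation-only when the positions are already symmetric
#' (ring starts), or with the gravity terms added for fully random starts.
#' The pool is then sorted by symmetry energy and truncated to the plan's
#' selection count.
#'
#' @param pool \code{structure_pool}.
#' @param restraints \code{symmetry_restraints} or a list of them.
#' @param plan \code{\link{stage_plan}}.
#' @param mode \code{"orientation"} (positions fixed) or \code{"full"}
#'   (gravity terms added, all 6 DOF).
#' @param sym_weight stage weight of the symmetry term. With few backbone
#'   beads per monomer the restraint count (which grows linearly with the
#'   bead count) is far below that of a real protein; scaling the term up
#'   restores a protein-like per-ring restraint stiffness.
#' @return sorted, truncated \code{structure_pool} with a
#'   \code{symmetry} score column.
#' @export
pre_assembly_stage <- function(pool, restraints, plan = stage_plan(),
                               mode = c("orientation", "full"),
                               sym_weight = 1) {
  mode <- match.arg(mode)
  tmpl <- pool_assembly(pool, 1)
  stack <- if (mode == "orientation")
    energy_stack(term_symmetry(restraints, tmpl, weight = sym_weight))
  else energy_stack(term_symmetry(restraints, tmpl, weight = sym_weight),
                    term_gravity())
  n <- pool_size(pool)
  esym <- numeric(n)
  for (i in seq_len(n)) {
    asm <- pool_assembly(pool, i)
    res <- if (mode == "orientation")
      orientation_only_minimize(asm, stack,
                                list(max_iter = plan$preassembly_iter))
    else minimize(asm, stack, list(max_iter = plan$preassembly_iter))
    pool$structures[[i]] <- res$assembly$poses
    esym[i] <- unname(res$energies["symmetry"])
  }
  pool$scores$symmetry <- esym
  pool$scores$stage <- "preassembly"
  pool <- pool_reorder(pool, order(esym))
  pool_truncate(pool, plan$preassembly_keep)
}

#' EM-fit configuration for the assembly / refinement stages
#'
#' @param resolution working resolution of the map (Angstrom).
#' @param F intermolecular spillover factor (>= 1).
#' @param cap voxel atom density cap.
#' @param k_hard,k_soft,k_clash penalty constants.
#' @param deconvolve deconvolve the map before precomputing overlaps.
#' @return list of class \code{emfit_config}.
#' @export
emfit_config <- function(resolution, F = 1, cap, k_hard = 100, k_soft = 1,
                         k_clash = 1, deconvolve = TRUE) {
  if (F < 1) stop("F must be >= 1")
  structure(list(resolution = resolution, F = F, cap = cap,
                 k_hard = k_hard, k_soft = k_soft, k_clash = k_clash,
                 deconvolve = deconvolve),
            class = "emfit_config")
}

# Shared preparation: deconvolved map -> overlap grid + calibration table.
# The stage overlap grids use a 2x stored lattice (speed); the voxel atom
# density (clash) always lives on the map geometry the caps were
# calibrated on.
prepare_em_terms <- function(pool, map, cfg) {
  src <- if (cfg$deconvolve)
    deconvolve(map, sigma_from_resolution(cfg$resolution))
  else map
  ogrid <- precompute_overlap_grid(src, gaussian_params(cfg$resolution),
                                   upsample = 2L)
  tab <- max_overlap_table(pool_assembly(pool, 1), cfg$resolution,
                           F = cfg$F, deconvolve = cfg$deconvolve)
  list(ogrid = ogrid, table = tab)
}

#' Assembly stage: fit all components into the coarse map
#'
#' Per structure, minimizes EM fit + voxel-density clash + symmetry +
#' gravity; records the final total energy and sorts ascending. Structures
#' whose energies go non-finite are dropped and counted.
#'
#' @param pool \code{structure_pool} (after pre-assembly).
#' @param map coarse \code{density_grid} (typically 40 A).
#' @param cfg \code{\link{emfit_config}} for the coarse map.
#' @param restraints symmetry restraints.
#' @param plan \code{\link{stage_plan}}.
#' @param sym_weight symmetry-term stage weight (see
#'   \code{\link{pre_assembly_stage}}).
#' @param gravity_weight stage weight of the gravity terms. Gravity exists
#'   to pull stray components toward the complex; once the density terms
#'   are active it must stay weak or it biases peripheral components
#'   toward the center of mass (default 0.01 on the normalized energy
#'   scale).
#' @return sorted \code{structure_pool} with a \code{total} score column;
#'   attribute \code{"n_dropped"} counts failed structures.
#' @export
assembly_stage <- function(pool, map, cfg, restraints, plan = stage_plan(),
                           sym_weight = 1, gravity_weight = 0.01) {
  tmpl <- pool_assembly(pool, 1)
  em <- prepare_em_terms(pool, map, cfg)
  stack <- energy_stack(
    term_em(em$ogrid, em$table, cfg$k_hard, cfg$k_soft),
    term_clash(map, cfg$cap, cfg$k_clash),
    term_symmetry(restraints, tmpl, weight = sym_weight),
    term_gravity(weight = gravity_weight))
  n <- pool_size(pool)
  etot <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    res <- tryCatch(
      minimize(pool_assembly(pool, i), stack,
               list(max_iter = plan$assembly_iter)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$energy)) next
    pool$structures[[i]] <- res$assembly$poses
    etot[i] <- res$energy
  }
  dropped <- sum(!is.finite(etot))
  keep <- which(is.finite(etot))
  pool$structures <- pool$structures[keep]
  pool$scores <- pool$scores[keep, , drop = FALSE]
  pool$scores$total <- etot[keep]
  pool$scores$stage <- "assembly"
  pool <- pool_reorder(pool, order(pool$scores$total))
  attr(pool, "n_dropped") <- dropped
  pool
}

#' Scoring stage: truncate by assembly energy, re-rank by GVM
#'
#' @param pool \code{structure_pool} sorted by assembly energy.
#' @param map fine \code{density_grid} (the original scoring-resolution
#'   map).
#' @param cfg \code{\link{gvm_config}}.
#' @param plan \code{\link{stage_plan}} (its \code{scoring_keep} is the
#'   truncation count).
#' @return GVM-ranked \code{structure_pool}.
#' @export
scoring_stage <- function(pool, map, cfg = gvm_config(),
                          plan = stage_plan()) {
  if (pool_size(pool) == 0) stop("empty pool")
  pool <- pool_truncate(pool, plan$scoring_keep)
  pool <- rank_by_gvm(pool, map, cfg)
  pool$scores$stage <- "scoring"
  pool
}

#' Refinement stage: staged minimization with the force field
#'
#' Four sub-stage minimizations per structure with the scheduled weights:
#' (a) fine-map EM + clash + symmetry, force field off; (b) force field at
#' weight 0.01; (c) force field at full weight, EM scaled by 50 to prevent
#' disintegration; (d) both at weight 1. Finally the pool is re-ranked by
#' GVM.
#'
#' @param pool \code{structure_pool} (GVM-ranked).
#' @param map fine \code{density_grid}.
#' @param cfg \code{\link{emfit_config}} for the fine map (use the
#'   refinement density cap).
#' @param restraints symmetry restraints.
#' @param ff_params \code{\link{pair_potential_params}}.
#' @param gvm_cfg \code{\link{gvm_config}} for the final re-ranking.
#' @param plan \code{\link{stage_plan}}.
#' @param ff_schedule force-field weights of the four sub-stages.
#' @param em_schedule EM-term weights of the four sub-stages.
#' @return refined, GVM-ranked \code{structure_pool}.
#' @export
refinement_stage <- function(pool, map, cfg, restraints, ff_params,
                             gvm_cfg = gvm_config(), plan = stage_plan(),
                             ff_schedule = c(0, 0.01, 1, 1),
                             em_schedule = c(1, 1, 50, 1),
                             sym_weight = 1) {
  pool <- pool_truncate(pool, plan$refine_keep)
  tmpl <- pool_assembly(pool, 1)
  em <- prepare_em_terms(pool, map, cfg)
  n <- pool_size(pool)
  for (sub in seq_along(ff_schedule)) {
    stack <- energy_stack(
      term_em(em$ogrid, em$table, cfg$k_hard, cfg$k_soft,
              weight = em_schedule[sub]),
      term_clash(map, cfg$cap, cfg$k_clash),
      term_symmetry(restraints, tmpl, weight = sym_weight),
      term_forcefield(ff_params, weight = ff_schedule[sub]))
    for (i in seq_len(n)) {
      res <- minimize(pool_assembly(pool, i), stack,
                      list(max_iter = plan$refine_iter))
      pool$structures[[i]] <- res$assembly$poses
      pool$scores$total[i] <- res$energy
    }
  }
  pool$scores$stage <- "refinement"
  rank_by_gvm(pool, map, gvm_cfg)
}

# ---- recombination ---------------------------------------------------------

#' Recombination scheme
#'
#' @param blocks list of integer vectors partitioning the component indices
#'   (e.g. one block per ring).
#' @param patterns list of integer vectors: which blocks a child takes from
#'   the second parent (proper nonempty subsets of the blocks).
#' @return list of class \code{recombination_scheme}.
#' @export
recombination_scheme <- function(blocks, patterns) {
  all_comp <- sort(unlist(blocks))
  if (any(duplicated(unlist(blocks))))
    stop("blocks must partition the components (duplicates found)")
  nb <- length(blocks)
  for (p in patterns) {
    if (length(p) == 0 || length(p) >= nb || any(!p %in% seq_len(nb)))
      stop("patterns must be proper nonempty subsets of the blocks")
  }
  structure(list(blocks = blocks, patterns = patterns),
            class = "recombination_scheme")
}

#' Recombine the top structures of a pool
#'
#' For every ordered pair of distinct parents among the top P structures
#' and every swap pattern, a child takes the pattern blocks' poses from the
#' second parent and the rest from the first. Children are pooled with the
#' parents; bit-identical children are removed. With P parents and m
#' patterns this yields P*(P-1)*m children before deduplication (19 800 for
#' P = 100, m = 2).
#'
#' @param pool \code{structure_pool} (ranked; the top \code{top_p} are the
#'   parents).
#' @param scheme \code{\link{recombination_scheme}}.
#' @param top_p number of parents (default: whole pool).
#' @return \code{structure_pool} of parents + children; column
#'   \code{parent1}/\code{parent2} record provenance.
#' @export
recombine <- function(pool, scheme, top_p = pool_size(pool)) {
  P <- min(top_p, pool_size(pool))
  if (P < 2) stop("recombination needs at least 2 parents")
  parents <- pool_truncate(pool, P)
  blocks <- scheme$blocks
  # block keys for cheap bit-identical dedup
  bkey <- matrix("", P, length(blocks))
  for (i in seq_len(P)) for (b in seq_along(blocks)) {
    bkey[i, b] <- paste(vapply(blocks[[b]], function(ci) {
      p <- parents$structures[[i]][[ci]]
      paste(c(p$R, p$t), collapse = ",")
    }, ""), collapse = ";")
  }
  maxc <- P * (P - 1) * length(scheme$patterns)
  structures <- c(parents$structures, vector("list", maxc))
  p1 <- rep(NA_integer_, P + maxc); p2 <- rep(NA_integer_, P + maxc)
  keys <- apply(bkey, 1, paste, collapse = "|")
  seen <- new.env(parent = emptyenv())
  for (k in keys) assign(k, TRUE, envir = seen)
  nstr <- P
  for (a in seq_len(P)) for (b in seq_len(P)) {
    if (a == b) next
    for (pat in scheme$patterns) {
      kb <- bkey[a, ]
      kb[pat] <- bkey[b, pat]
      key <- paste(kb, collapse = "|")
      if (!is.null(seen[[key]])) next
      assign(key, TRUE, envir = seen)
      child <- parents$structures[[a]]
      for (blk in pat) for (ci in blocks[[blk]])
        child[[ci]] <- parents$structures[[b]][[ci]]
      nstr <- nstr + 1L
      structures[[nstr]] <- child
      p1[nstr] <- a; p2[nstr] <- b
    }
  }
  structures <- structures[seq_len(nstr)]
  scores <- data.frame(stage = rep("recombined", nstr),
                       parent1 = p1[seq_len(nstr)], parent2 = p2[seq_len(nstr)])
  scores$stage[seq_len(P)] <- parents$scores$stage
  structure_pool(parents$models, structures, scores)
}

#' Cut a ranked pool at the largest relative GVM energy gap
#'
#' Generalizes the energy-gap selection of well-separated solutions: within
#' the top \code{max_count} structures, the pool is cut after the largest
#' relative gap in sorted GVM energy, falling back to \code{max_count} when
#' no gap stands out (largest gap below \code{min_factor} times the median
#' gap).
#'
#' @param pool GVM-ranked \code{structure_pool}.
#' @param max_count upper bound on the selection.
#' @param min_factor gap dominance factor for the fallback.
#' @return truncated \code{structure_pool}.
#' @export
select_by_energy_gap <- function(pool, max_count, min_factor = 5) {
  n <- min(max_count, pool_size(pool))
  e <- pool$scores$gvm[seq_len(n)]
  if (is.null(e) || n < 3) return(pool_truncate(pool, n))
  gaps <- diff(e)
  med <- median(gaps)
  i <- which.max(gaps)
  if (med > 0 && gaps[i] >= min_factor * med)
    pool_truncate(pool, i)
  else pool_truncate(pool, n)
}

# ---- full protocol ---------------------------------------------------------

#' Run the full multi-stage assembly protocol
#'
#' Starting structures -> pre-assembly (symmetry) -> assembly into the
#' coarse map -> GVM scoring against the fine map -> optional recombination
#' rounds -> staged refinement -> final GVM ranking.
#'
#' @param config list with fields:
#'   \describe{
#'     \item{starts}{either a \code{structure_pool}, or
#'       \code{list(type="ring", rings=...)} /
#'       \code{list(type="random", models=, box=)}.}
#'     \item{coarse_map, fine_map}{\code{density_grid}s.}
#'     \item{em_coarse, em_fine}{\code{\link{emfit_config}}s.}
#'     \item{restraints}{symmetry restraints (list).}
#'     \item{gvm}{\code{\link{gvm_config}}.}
#'     \item{ff_params}{\code{\link{pair_potential_params}}.}
#'     \item{plan}{\code{\link{stage_plan}}.}
#'     \item{recombination}{optional \code{list(scheme=, rounds=1)}.}
#'     \item{seed}{master seed.}
#'     \item{reference}{optional reference \code{assembly} for RMSD
#'       reporting.}
#'     \item{equivalences}{optional component relabelings for
#'       \code{\link{assembly_rmsd}}.}
#'   }
#' @return object of class \code{em_protocol_result}: the final ranked
#'   \code{pool}, per-stage \code{stats}, and an RMSD table when a
#'   reference was supplied.
#' @export
run_protocol <- function(config) {
  cfg <- config
  seed <- if (is.null(cfg$seed)) 1 else cfg$seed
  plan <- if (is.null(cfg$plan)) stage_plan() else cfg$plan
  gvm_cfg <- if (is.null(cfg$gvm)) gvm_config() else cfg$gvm
  t0 <- proc.time()[3]
  stats <- list()
  note <- function(stage, pool) {
    keys <- intersect(c("symmetry", "total", "gvm"), names(pool$scores))
    qs <- lapply(keys, function(k)
      unname(quantile(pool$scores[[k]], c(0, 0.5, 1), na.rm = TRUE)))
    names(qs) <- keys
    stats[[stage]] <<- list(n = pool_size(pool), energy_quantiles = qs,
                            elapsed_s = unname(proc.time()[3] - t0))
  }

  pool <- if (inherits(cfg$starts, "structure_pool")) cfg$starts
  else if (cfg$starts$type == "ring")
    ring_topology_starts(cfg$starts$rings, plan$n_starts, seed)
  else random_starts(cfg$starts$models, plan$n_starts, cfg$starts$box, seed)
  note("starts", pool)

  sym_w <- if (is.null(cfg$symmetry_weight)) 1 else cfg$symmetry_weight
  mode <- if (!inherits(cfg$starts, "structure_pool") &&
              cfg$starts$type == "ring") "orientation" else "full"
  pool <- pre_assembly_stage(pool, cfg$restraints, plan, mode = mode,
                             sym_weight = sym_w)
  note("preassembly", pool)

  grav_w <- if (is.null(cfg$gravity_weight)) 0.01 else cfg$gravity_weight
  pool <- assembly_stage(pool, cfg$coarse_map, cfg$em_coarse,
                         cfg$restraints, plan, sym_weight = sym_w,
                         gravity_weight = grav_w)
  note("assembly", pool)

  pool <- scoring_stage(pool, cfg$fine_map, gvm_cfg, plan)
  note("scoring", pool)

  if (!is.null(cfg$recombination)) {
    rounds <- if (is.null(cfg$recombination$rounds)) 1
              else cfg$recombination$rounds
    for (r in seq_len(rounds)) {
      pool <- recombine(pool, cfg$recombination$scheme,
                        top_p = min(plan$recombine_top, pool_size(pool)))
      pool <- rank_by_gvm(pool, cfg$fine_map, gvm_cfg)
      pool <- pool_truncate(pool, plan$scoring_keep)
      note(paste0("recombination_", r), pool)
    }
  }

  pool <- refinement_stage(pool, cfg$fine_map, cfg$em_fine, cfg$restraints,
                           cfg$ff_params, gvm_cfg, plan, sym_weight = sym_w)
  note("refinement", pool)

  # post-refinement recombination: refined structures carry fully settled
  # ring blocks, so recombining them (and briefly re-refining the best)
  # assembles complementary correct blocks from different parents
  if (!is.null(cfg$recombination)) {
    pool <- recombine(pool, cfg$recombination$scheme,
                      top_p = pool_size(pool))
    pool <- rank_by_gvm(pool, cfg$fine_map, gvm_cfg)
    pool <- pool_truncate(pool, plan$refine_keep)
    pool <- refinement_stage(pool, cfg$fine_map, cfg$em_fine,
                             cfg$restraints, cfg$ff_params, gvm_cfg, plan,
                             ff_schedule = 1, em_schedule = 1,
                             sym_weight = sym_w)
    note("recombination_final", pool)
  }

  rmsd_table <- NULL
  if (!is.null(cfg$reference)) {
    rmsd_table <- data.frame(
      rank = seq_len(pool_size(pool)),
      gvm = pool$scores$gvm,
      rmsd = vapply(seq_len(pool_size(pool)), function(i)
        assembly_rmsd(pool_assembly(pool, i), cfg$reference,
                      cfg$equivalences), 0))
  }
  structure(list(pool = pool, stats = stats, rmsd_table = rmsd_table,
                 seed = seed, plan = plan),
            class = "em_protocol_result")
}

#' @export
print.em_protocol_result <- function(x, ...) {
  cat("em_protocol_result (seed ", x$seed, ")\n", sep = "")
  for (s in names(x$stats))
    cat(sprintf("  %-16s n = %6d  (%.1f s)\n", s, x$stats[[s]]$n,
                x$stats[[s]]$elapsed_s))
  if (!is.null(x$rmsd_table)) {
    cat("  top models (rank, GVM, RMSD):\n")
    print(head(x$rmsd_table, 5), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.em_protocol_result <- function(object, ...) {
  print(object)
  if (!is.null(object$rmsd_table))
    cat("best RMSD in final pool:",
        signif(min(object$rmsd_table$rmsd), 4), "A\n")
  invisible(object)
}

#' @export
plot.em_protocol_result <- function(x, ...) {
  if (is.null(x$rmsd_table)) {
    plot(x$pool$scores$gvm, xlab = "rank", ylab = "GVM energy",
         main = "final ranking", ...)
  } else {
    plot(x$rmsd_table$rmsd, x$rmsd_table$gvm, xlab = "RMSD to reference (A)",
         ylab = "GVM energy", main = "GVM energy vs model accuracy", ...)
  }
  invisible(x)
}

#' Write the per-stage protocol report as JSON
#'
#' Counts, energy quantiles and timings per stage, plus the RMSD table
#' when a reference was supplied.
#'
#' @param result \code{em_protocol_result}.
#' @param path output path.
#' @export
write_protocol_report <- function(result, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("writing the JSON report requires the jsonlite package")
  report <- list(seed = result$seed, stages = result$stats)
  if (!is.null(result$rmsd_table)) report$rmsd_table <- result$rmsd_table
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = 8,
                       dataframe = "columns")
  invisible(path)
}

#' Write the ranked models of a pool as PDB files + a score table
#'
#' @param pool \code{structure_pool}.
#' @param dir output directory.
#' @param n number of top models to write.
#' @return path of the score table (tab-separated: rank, file, scores).
#' @export
write_ranked_models <- function(pool, dir, n = 10) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- min(n, pool_size(pool))
  files <- character(n)
  for (i in seq_len(n)) {
    cc <- assembly_coords(pool_assembly(pool, i))
    files[i] <- file.path(dir, sprintf("model_%03d.pdb", i))
    nb <- nrow(cc$xyz)
    bio3d::write.pdb(file = files[i], xyz = as.numeric(t(cc$xyz)),
                     resno = seq_len(nb), chain = rep("A", nb),
                     resid = rep("ALA", nb),
                     elety = ifelse(cc$kind == "CA", "CA", "CB"))
  }
  tab <- cbind(rank = seq_len(n), file = basename(files),
               pool$scores[seq_len(n), , drop = FALSE])
  out <- file.path(dir, "scores.tsv")
  write.table(tab, out, sep = "\t", row.names = FALSE, quote = FALSE)
  out
}
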
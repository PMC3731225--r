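#' Perturb one regulatory link by a signed fraction
#'
#' Scales the link strength to `(1 + delta) * current`, using the global
#' default (`p$a` or `p$b`) as the base when the edge has no explicit
#' strength. `delta = 0` leaves the dynamics identical everywhere.
#'
#' @param net a [grn].
#' @param source,target,sign edge identification (see
#'   [set_link_strength()]).
#' @param delta signed fraction, must exceed -1.
#' @param p kinetic parameters supplying the default base strength.
#' @return The perturbed [grn] (copy).
#' @export
perturb_link <- function(net, source, target, sign, delta, p) {
  if (delta <= -1) stop("delta must be > -1 (strength must remain positive)")
  i <- find_edge(net, source, target, sign)
  base <- net$edges$strength[i]
  if (is.na(base)) base <- if (sign == "act") p$a else p$b
  net$edges$strength[i] <- (1 + delta) * base
  net
}

#' Knock down a gene
#'
#' Removes every production term into the gene (all incoming activation
#' and repression links), leaving only first-order degradation so its
#' level decays to zero. Outgoing links remain and transmit the decayed
#' level.
#'
#' @param net a [grn].
#' @param gene gene name or id.
#' @return The modified [grn] (copy).
#' @export
knockdown_gene <- function(net, gene) {
  g <- resolve_nodes(gene, net$nodes)
  net$edges <- net$edges[net$edges$target != g, , drop = FALSE]
  rownames(net$edges) <- NULL
  net
}

# Shared metric engine: barrier heights (from a Langevin histogram
# landscape over the two marker axes) and/or both-direction MFPTs, under
# a fixed seed protocol so perturbation deltas are seed-matched.
landscape_metrics <- function(net, p, metrics, cfg, axes, att_ref,
                              bins = 40, mfpt_passages = 60,
                              mfpt_max_steps = 2e6, n_starts = 200,
                              att_seed = 1) {
  att <- find_attractors(net, p, n_starts = n_starts, seed = att_seed)
  if (nrow(att$states) < 2) stop("monostable system after perturbation")
  # order attractors to the baseline reference (stem first)
  d1 <- apply(att$states, 1, function(s) max(abs(s - att_ref[[1]])))
  stem_i <- which.min(d1)
  d2 <- apply(att$states, 1, function(s) max(abs(s - att_ref[[2]])))
  diff_i <- which.min(d2)
  if (stem_i == diff_i) stop("attractors do not separate against references")
  s_stem <- att$states[stem_i, ]; s_diff <- att$states[diff_i, ]
  out <- list(stem = s_stem, diff = s_diff)
  if ("barrier" %in% metrics) {
    cfg_land <- sim_config(dt = cfg$dt, steps = cfg$steps, D = cfg$D,
                           seed = cfg$seed, record_every = 10L)
    traj <- simulate_network(net, p, s_stem, cfg_land)
    land <- histogram_landscape(traj, axes, bins = bins,
                                lims = list(x = c(0, 2.5), y = c(0, 2.5)))
    br <- barrier_heights(land,
                          order_by = list(s_stem[axes], s_diff[axes]))
    out$barrier_stem <- br$barrier1
    out$barrier_diff <- br$barrier2
  }
  if ("mfpt" %in% metrics) {
    cfg_m <- sim_config(dt = cfg$dt, steps = cfg$steps, D = cfg$D,
                        seed = cfg$seed + 1L)
    out$mfpt_diff <- estimate_mfpt(net, p, cfg_m, s_stem, s_diff,
                                   n_passages = mfpt_passages,
                                   max_steps = mfpt_max_steps)$mean
    cfg_m$seed <- cfg$seed + 2L
    out$mfpt_repro <- estimate_mfpt(net, p, cfg_m, s_diff, s_stem,
                                    n_passages = mfpt_passages,
                                    max_steps = mfpt_max_steps)$mean
  }
  out
}

#' Global sensitivity scan over links or genes
#'
#' For each target, rebuilds the perturbed system (link strength scaled
#' by `1 + delta`, or gene knocked down), recomputes barrier heights
#' and/or mean first passage times under the *same* seeds as the cached
#' baseline, and reports the deltas. Failing targets (e.g. monostable
#' after perturbation) are flagged and the scan continues.
#'
#' @param net a [grn].
#' @param p a [hill_params].
#' @param targets data frame of links (`source`, `target`, `sign`) and/or
#'   character vector of gene names (knockdowns). A data frame may mix
#'   both by giving `gene` rows with `sign == "knockdown"`.
#' @param delta signed perturbation fraction applied to every link
#'   target (default +0.2, i.e. +20%).
#' @param metrics subset of `c("barrier", "mfpt")`.
#' @param cfg a [sim_config] used for every metric evaluation (its seed
#'   is the common-seed protocol).
#' @param axes two marker genes for the landscape projection.
#' @param ... tuning passed to the internal metric engine
#'   (`bins`, `mfpt_passages`, `mfpt_max_steps`, `n_starts`).
#' @return Object of class `grn_sensitivity`: a data frame with one row
#'   per target (deltas of each metric, `ok` flag), with the baseline
#'   metrics stored as attribute `baseline`.
#' @export
sensitivity_scan <- function(net, p, targets, delta = 0.2,
                             metrics = c("barrier", "mfpt"), cfg,
                             axes, ...) {
  stopifnot(nrow(targets) >= 1)
  metrics <- match.arg(metrics, several.ok = TRUE)
  att0 <- find_attractors(net, p, n_starts = 200, seed = 1)
  if (nrow(att0$states) < 2) stop("baseline system is not bistable")
  o <- order(-(att0$states[, axes[1]] - att0$states[, axes[2]]))
  refs <- list(att0$states[o[1], ], att0$states[o[length(o)], ])
  base <- landscape_metrics(net, p, metrics, cfg, axes, refs, ...)
  rows <- vector("list", nrow(targets))
  for (i in seq_len(nrow(targets))) {
    tg <- targets[i, , drop = FALSE]
    is_kd <- identical(tg$sign, "knockdown")
    pert <- tryCatch({
      if (is_kd) knockdown_gene(net, tg$gene)
      else perturb_link(net, tg$source, tg$target, tg$sign, delta, p)
    }, error = function(e) e)
    lab <- if (is_kd) paste0("KD:", tg$gene)
           else paste0(tg$source, ifelse(tg$sign == "act", "->", "-|"), tg$target)
    rec <- data.frame(target = lab, delta = if (is_kd) NA_real_ else delta,
                      ok = FALSE,
                      delta_barrier_stem = NA_real_,
                      delta_barrier_diff = NA_real_,
                      delta_mfpt_diff = NA_real_,
                      delta_mfpt_repro = NA_real_,
                      stringsAsFactors = FALSE)
    if (!inherits(pert, "error")) {
      met <- tryCatch(landscape_metrics(pert, p, metrics, cfg, axes, refs, ...),
                      error = function(e) e)
      if (!inherits(met, "error")) {
        rec$ok <- TRUE
        if ("barrier" %in% metrics) {
          rec$delta_barrier_stem <- met$barrier_stem - base$barrier_stem
          rec$delta_barrier_diff <- met$barrier_diff - base$barrier_diff
        }
        if ("mfpt" %in% metrics) {
          rec$delta_mfpt_diff <- met$mfpt_diff - base$mfpt_diff
          rec$delta_mfpt_repro <- met$mfpt_repro - base$mfpt_repro
        }
      }
    }
    rows[[i]] <- rec
  }
  res <- do.call(rbind, rows)
  attr(res, "baseline") <- base
  attr(res, "cfg") <- cfg
  class(res) <- c("grn_sensitivity", class(res))
  res
}

#' Rank scanned links by barrier impact
#'
#' Orders sensitivity records by `|delta_barrier_stem| +
#' |delta_barrier_diff|` descending (ties broken by target label) and
#' returns the `top_k` most critical links.
#'
#' @param records a `grn_sensitivity` (records must share one `delta`).
#' @param top_k how many to return.
#' @return The reordered top rows.
#' @export
rank_links <- function(records, top_k = nrow(records)) {
  d <- records$delta[!is.na(records$delta)]
  if (length(unique(d)) > 1)
    stop("records mix different perturbation fractions")
  score <- abs(records$delta_barrier_stem) + abs(records$delta_barrier_diff)
  o <- order(-score, records$target)
  utils::head(records[o, , drop = FALSE], top_k)
}

#' Activation annealing schedule
#'
#' @param a_start,a_end start and end activation constants (distinct).
#' @param rate ramp rate (activation units per time, > 0).
#' @param form `"linear"` or `"exponential"` ramp in time.
#' @return Object of class `anneal_schedule`.
#' @export
anneal_schedule <- function(a_start, a_end, rate = 0.001,
                            form = c("linear", "exponential")) {
  if (a_start == a_end) stop("a_start and a_end must differ")
  stopifnot(rate > 0, a_start > 0, a_end > 0)
  structure(list(a_start = a_start, a_end = a_end, rate = rate,
                 form = match.arg(form)), class = "anneal_schedule")
}

schedule_values <- function(sch, dt) {
  total_t <- abs(sch$a_end - sch$a_start) / sch$rate
  n <- max(2L, ceiling(total_t / dt))
  if (sch$form == "linear") {
    seq(sch$a_start, sch$a_end, length.out = n)
  } else {
    lam <- log(sch$a_start / sch$a_end) / total_t
    sch$a_start * exp(-lam * seq(0, total_t, length.out = n))
  }
}

#' Activation annealing and hysteresis
#'
#' Runs a Langevin trajectory while the strength of the selected
#' activation links follows the schedule `a(t)`, detecting the
#' differentiation jump (the projected marker code first matching the
#' destination attractor's code for `debounce` consecutive recorded
#' samples) at critical activation `a_c1`; then repeats with the
#' reversed schedule from the differentiated state, giving the
#' reprogramming jump `a_c2`. For a bistable switch the two differ
#' (`a_c1 < a_c2`), tracing a hysteresis loop.
#'
#' @param net a [grn].
#' @param p a [hill_params].
#' @param schedule an [anneal_schedule] (forward = differentiation
#'   direction; its reverse is used for reprogramming).
#' @param cfg a [sim_config] (`steps` is ignored; the schedule fixes the
#'   duration).
#' @param stem_state,diff_state reference attractor states at the two
#'   schedule endpoints; codes are taken against the per-gene midpoint
#'   of the two references.
#' @param schedule_edges integer edge rows following `a(t)`; default all
#'   default-strength activation edges.
#' @param debounce consecutive matching samples required to call a jump.
#' @param sweeps run both sweep directions (default) or only the forward
#'   (differentiation) or reverse (reprogramming) sweep.
#' @return Object of class `grn_anneal`: `a_c1`, `a_c2` (NA for a sweep
#'   not run), recorded trajectories for the sweeps run.
#' @export
anneal_activation <- function(net, p, schedule, cfg, stem_state, diff_state,
                              schedule_edges = NULL, debounce = 10L,
                              sweeps = c("both", "forward", "reverse")) {
  sweeps <- match.arg(sweeps)
  stopifnot(inherits(schedule, "anneal_schedule"))
  sched_fwd <- schedule_values(schedule, cfg$dt)
  sched_rev <- rev(sched_fwd)
  cutoffs <- (stem_state + diff_state) / 2
  stem_code <- paste(as.integer(stem_state >= cutoffs), collapse = "")
  diff_code <- paste(as.integer(diff_state >= cutoffs), collapse = "")
  if (stem_code == diff_code)
    stop("reference states do not separate under midpoint cutoffs")
  run <- function(x0, sched, dest_code, seed) {
    cfg1 <- sim_config(dt = cfg$dt, steps = length(sched), D = cfg$D,
                       seed = seed, record_every = cfg$record_every)
    traj <- simulate_network(net, p, x0, cfg1, schedule = sched,
                             schedule_edges = schedule_edges)
    codes <- code_strings(binarize(traj, cutoffs = cutoffs)$codes)
    hit <- codes == dest_code
    # first index where `debounce` consecutive samples match
    runlen <- stats::filter(as.numeric(hit), rep(1, debounce), sides = 1)
    j <- which(runlen == debounce)[1]
    if (is.na(j)) return(list(a_c = NA_real_, traj = traj, sched = sched))
    jump_rec <- j - debounce + 1L
    step_idx <- min((jump_rec - 1L) * cfg$record_every + 1L, length(sched))
    list(a_c = sched[step_idx], traj = traj, sched = sched)
  }
  seed <- if (is.null(cfg$seed)) 1L else cfg$seed
  fwd <- if (sweeps != "reverse") run(stem_state, sched_fwd, diff_code, seed)
         else list(a_c = NA_real_)
  rev_ <- if (sweeps != "forward") run(diff_state, sched_rev, stem_code,
                                       seed + 1L)
          else list(a_c = NA_real_)
  if ((sweeps != "reverse" && is.na(fwd$a_c)) ||
      (sweeps != "forward" && is.na(rev_$a_c)))
    stop("no state jump detected within the schedule range; widen ",
         "[a_end, a_start] or slow the ramp")
  structure(list(a_c1 = fwd$a_c, a_c2 = rev_$a_c,
                 forward = fwd, reverse = rev_,
                 stem_code = stem_code, diff_code = diff_code),
            class = "grn_anneal")
}

#' @export
print.grn_anneal <- function(x, ...) {
  cat(sprintf("Annealing: a_c1 (differentiation) = %.4g, a_c2 (reprogramming) = %.4g%s\n",
              x$a_c1, x$a_c2,
              if (x$a_c1 < x$a_c2) " [hysteresis]" else ""))
  invisible(x)
}
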
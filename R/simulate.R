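#' Ground truth for a simulated digestion
#'
#' Defines the stochastic model of a folded substrate being digested by a
#' protease: each cleavage site (identified by its P1 residue) carries an
#' intrinsic rate constant and, optionally, an accessibility gate — a set of
#' prerequisite sites that must already be cut *on the same molecule* before
#' the site becomes cleavable. Gates are conjunctive (all prerequisites) and
#' must form an acyclic dependency graph. This formalises sequential
#' unfolding: early surface cuts relax the fold and expose buried bonds.
#'
#' @param substrate A [substrate_protein()].
#' @param sites A data frame with columns `p1` (integer, `1 <= p1 < length`),
#'   `rate` (per-second rate constant, `>= 0`) and optionally `gate` (a list
#'   column of integer vectors of prerequisite P1 positions; `NULL`/empty =
#'   ungated).
#' @param n_molecules Number of substrate copies in the simulated ensemble.
#' @param detectable_length Length window `(min, max)` in residues within
#'   which a proteolytic product is observable by MS. Default `c(7, 25)`:
#'   identification searches cover peptides up to 25 residues with a minimum
#'   length of 7.
#' @return An object of class `digestion_ground_truth`.
#' @examples
#' sub <- substrate_protein(strrep("A", 50))
#' gt <- digestion_ground_truth(
#'   sub,
#'   tibble::tibble(p1 = c(10L, 30L), rate = c(0.05, 0.01), gate = list(NULL, 10L)),
#'   n_molecules = 100
#' )
#' @export
digestion_ground_truth <- function(substrate, sites, n_molecules = 10000,
                                   detectable_length = c(7, 25)) {
  stopifnot(inherits(substrate, "substrate_protein"))
  sites <- as_tibble(sites)
  if (!all(c("p1", "rate") %in% names(sites))) {
    abort("sites must have columns p1 and rate")
  }
  if (!"gate" %in% names(sites)) sites$gate <- vector("list", nrow(sites))
  sites$p1 <- as.integer(sites$p1)
  sites$gate <- map(sites$gate, ~ as.integer(.x %||% integer()))
  if (anyDuplicated(sites$p1) > 0L) abort("duplicate P1 sites")
  if (any(sites$p1 < 1L | sites$p1 >= substrate$length)) {
    abort("P1 sites must satisfy 1 <= p1 < substrate length")
  }
  if (any(sites$rate < 0)) abort("rates must be non-negative")
  unknown <- setdiff(unlist(sites$gate), sites$p1)
  if (length(unknown) > 0L) {
    abort(paste0("gate references unknown P1 site(s): ", paste(unknown, collapse = ", ")))
  }
  topo_order_sites(sites) # errors on cycles
  structure(
    list(
      substrate = substrate,
      sites = sites,
      n_molecules = as.integer(n_molecules),
      detectable_length = as.integer(detectable_length)
    ),
    class = "digestion_ground_truth"
  )
}

# Kahn topological sort over the gate dependency graph; errors on cycles.
topo_order_sites <- function(sites) {
  p1 <- sites$p1
  deps <- setNames(sites$gate, as.character(p1))
  indeg <- map_int(deps, length)
  names(indeg) <- as.character(p1)
  order <- integer()
  ready <- p1[indeg[as.character(p1)] == 0L]
  remaining <- deps
  while (length(ready) > 0L) {
    v <- ready[1]
    ready <- ready[-1]
    order <- c(order, v)
    for (w in names(remaining)) {
      if (v %in% remaining[[w]]) {
        remaining[[w]] <- setdiff(remaining[[w]], v)
        if (length(remaining[[w]]) == 0L && !(as.integer(w) %in% order) &&
          !(as.integer(w) %in% ready)) {
          ready <- c(ready, as.integer(w))
        }
      }
    }
  }
  if (length(order) != length(p1)) {
    abort("gate dependency graph contains a cycle or unreachable gated site")
  }
  order
}

#' Simulate time-resolved digestion of a substrate ensemble
#'
#' Exact per-molecule stochastic simulation. On each molecule every cleavable
#' (uncut, gate-satisfied) bond fires as an independent exponential clock with
#' its intrinsic rate; firing a cut may unlock gated sites on that molecule.
#' Because the clocks are independent and a cut only ever unlocks further
#' sites, the firing time of site *i* on a molecule is distributed as
#' `max(firing times of its prerequisites) + Exponential(rate_i)`, which is
#' sampled exactly, site by site in topological order, for the whole ensemble
#' at once.
#'
#' @param ground_truth A [digestion_ground_truth()].
#' @param time_points Sorted ascending sampling times in seconds, starting at 0.
#' @param seed Integer seed; the simulation is fully reproducible given the seed.
#' @param protease_multiplier Global multiplier applied to all rates, modelling
#'   protease concentration (e.g. `0.1` for a ten-fold reduced protease).
#' @return An object of class `digestion_simulation` with the per-molecule
#'   event log (`events`: molecule, p1, time), the sampling times, and the
#'   ground truth.
#' @export
simulate_digestion <- function(ground_truth, time_points, seed,
                               protease_multiplier = 1) {
  stopifnot(inherits(ground_truth, "digestion_ground_truth"))
  time_points <- as.numeric(time_points)
  if (is.unsorted(time_points, strictly = TRUE) || time_points[1] != 0) {
    abort("time_points must be strictly ascending and start at 0")
  }
  sites <- ground_truth$sites
  n <- ground_truth$n_molecules
  order <- topo_order_sites(sites)
  fire <- matrix(Inf, nrow = n, ncol = nrow(sites),
                 dimnames = list(NULL, as.character(sites$p1)))
  withr::with_seed(seed, {
    for (p in order) {
      i <- match(p, sites$p1)
      k <- sites$rate[i] * protease_multiplier
      gate <- sites$gate[[i]]
      start_t <- if (length(gate) == 0L) {
        rep(0, n)
      } else {
        do.call(pmax, lapply(as.character(gate), function(g) fire[, g]))
      }
      wait <- if (k > 0) rexp(n, rate = k) else rep(Inf, n)
      fire[, as.character(p)] <- start_t + wait
    }
  })
  finite <- which(is.finite(fire))
  events <- tibble(
    molecule = as.integer((finite - 1L) %% n + 1L),
    p1 = sites$p1[(finite - 1L) %/% n + 1L],
    time = fire[finite]
  ) |>
    arrange(.data$molecule, .data$time)
  structure(
    list(
      events = events,
      time_points = time_points,
      ground_truth = ground_truth,
      seed = seed,
      protease_multiplier = protease_multiplier
    ),
    class = "digestion_simulation"
  )
}

#' @export
print.digestion_simulation <- function(x, ...) {
  cat(
    "<digestion_simulation> ", x$ground_truth$n_molecules, " molecules, ",
    nrow(x$ground_truth$sites), " sites, ", nrow(x$events), " cleavage events, ",
    length(x$time_points), " time points\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.digestion_simulation <- function(x, ...) x$events

#' @export
glance.digestion_simulation <- function(x, ...) {
  tibble(
    n_molecules = x$ground_truth$n_molecules,
    n_sites = nrow(x$ground_truth$sites),
    n_events = nrow(x$events),
    t_max = max(x$time_points)
  )
}

#' Cut states of every molecule at one time point
#'
#' @param simulation A [simulate_digestion()] result.
#' @param time_point Time in seconds.
#' @return A list of sorted integer vectors, one per molecule, of fired P1 sites.
#' @export
molecule_states <- function(simulation, time_point) {
  ev <- filter(simulation$events, .data$time <= time_point)
  states <- rep(list(integer()), simulation$ground_truth$n_molecules)
  if (nrow(ev) > 0L) {
    sp <- split(ev$p1, ev$molecule)
    states[as.integer(names(sp))] <- map(sp, ~ sort(as.integer(.x)))
  }
  states
}

#' Tally peptide products from simulated molecule states
#'
#' Converts each molecule's cut set at each sampling time into its maximal
#' product intervals and tallies them across the ensemble. Intervals whose
#' length falls inside the detectable window are observable; the rest are kept,
#' flagged unobservable, so that residue mass balance can be checked.
#'
#' @param simulation A [simulate_digestion()] result.
#' @param detectable_length Length window, defaulting to the ground truth's.
#' @return A tibble with `time_s`, `start`, `end`, `length`, `count`
#'   (molecules carrying that product) and `observable`.
#' @export
peptides_from_states <- function(simulation,
                                 detectable_length = simulation$ground_truth$detectable_length) {
  L <- simulation$ground_truth$substrate$length
  n <- simulation$ground_truth$n_molecules
  out <- map(simulation$time_points, function(tp) {
    ev <- simulation$events |>
      filter(.data$time <= tp) |>
      arrange(.data$molecule, .data$p1)
    if (nrow(ev) == 0L) {
      return(tibble(time_s = tp, start = 1L, end = L, count = n))
    }
    ev <- ev |>
      group_by(.data$molecule) |>
      mutate(seg_start = lag(.data$p1, default = 0L) + 1L) |>
      ungroup()
    internal <- tibble(start = ev$seg_start, end = ev$p1)
    tails <- ev |>
      group_by(.data$molecule) |>
      summarise(start = max(.data$p1) + 1L, .groups = "drop") |>
      mutate(end = L) |>
      select("start", "end")
    n_intact <- n - n_distinct(ev$molecule)
    pieces <- bind_rows(internal, tails)
    if (n_intact > 0L) {
      pieces <- bind_rows(pieces, tibble(start = rep(1L, n_intact), end = rep(L, n_intact)))
    }
    pieces |>
      count(.data$start, .data$end, name = "count") |>
      mutate(time_s = tp)
  })
  bind_rows(out) |>
    mutate(
      length = .data$end - .data$start + 1L,
      observable = .data$length >= detectable_length[1] &
        .data$length <= detectable_length[2]
    ) |>
    select("time_s", "start", "end", "length", "count", "observable") |>
    arrange(.data$time_s, .data$start, .data$end)
}

#' Add measurement noise and controls to a simulated abundance table
#'
#' Turns observable product abundances into replicate intensity measurements:
#' `intensity = scale * abundance * LogNormal(0, sigma)`, drawn independently
#' per replicate and zeroed with probability `dropout` (non-detection).
#' Protease-free control samples carry zero intensity for every product.
#'
#' @param abundance Output of [peptides_from_states()] (only observable rows
#'   are measured).
#' @param replicates Number of replicates per condition and time point.
#' @param sigma_lognormal Log-normal sdlog of the multiplicative noise.
#' @param dropout_probability Probability that a measurement is missed.
#' @param intensity_scale Intensity units per molecule.
#' @param detection_limit Minimum product abundance (molecules) that the
#'   instrument can register; lower-abundance products measure 0. Default 0
#'   (no floor).
#' @param seed Integer seed.
#' @return A tibble with `condition` (`"digest"`/`"control"`), `replicate`,
#'   `time_s`, `start`, `end`, `abundance` and `intensity`.
#' @export
add_noise <- function(abundance, replicates = 4, sigma_lognormal = 0.5,
                      dropout_probability = 0.2, intensity_scale = 1e6,
                      detection_limit = 0, seed = 1L) {
  stopifnot(sigma_lognormal >= 0, dropout_probability >= 0, dropout_probability < 1)
  obs <- filter(abundance, .data$observable) |>
    mutate(count = ifelse(.data$count < detection_limit, 0L, .data$count))
  digest <- crossing(obs, replicate = seq_len(replicates)) |>
    mutate(condition = "digest")
  withr::with_seed(seed, {
    noise <- rlnorm(nrow(digest), meanlog = 0, sdlog = sigma_lognormal)
    dropped <- runif(nrow(digest)) < dropout_probability
  })
  digest <- digest |>
    mutate(intensity = ifelse(dropped, 0, intensity_scale * .data$count * noise))
  control <- crossing(obs, replicate = seq_len(replicates)) |>
    mutate(condition = "control", intensity = 0)
  bind_rows(digest, control) |>
    rename(abundance = "count") |>
    select("condition", "replicate", "time_s", "start", "end", "abundance", "intensity") |>
    arrange(.data$condition, .data$time_s, .data$start, .data$end, .data$replicate)
}

#' Default simulated scenario: a 346-residue pseudo-substrate
#'
#' A fixed 346-residue pseudo-substrate (same length as a four-repeat annexin
#' core plus N-terminal domain) with a known unfolding hierarchy: three fast,
#' ungated surface sites (P1 41, 82, 107), six gated second-wave sites
#' unlocked by the surface cuts, and a slow four-site C-terminal block that is
#' digested last. Eleven ungated minor sites (low intrinsic rate) are
#' scattered along the chain, mirroring the secondary low-affinity cuts seen
#' around major sites in real digests; they also ensure each major site has an
#' observable flanking product. This gives downstream order-inference a known
#' truth to recover.
#'
#' @param n_molecules Ensemble size.
#' @param detectable_length Observable peptide length window.
#' @param rate_scale Multiplier on all intrinsic rates.
#' @return A [digestion_ground_truth()].
#' @export
scenario_pseudo_anxa1 <- function(n_molecules = 10000, detectable_length = c(7, 25),
                                  rate_scale = 1) {
  seq346 <- paste0(
    "MKVYRVRPLEHWQGLFYLSSMNSAVSAGRKSEDSAEGVGHFAKISCEMQRIWIDLGPLPT",
    "PNPKSTFIGANPPVKNNLEMRQFHMHRAVDGVAVKDGINTDRARDHCALNVGLVYSIGEK",
    "VTAICPPLKPIKAQLGLWYYKMAVVRWGLAIHSEFIAYNPLKPQVCNKAVDYRVHYVLLR",
    "TRSNPAVDAKRDIRHMCTYLLRDNGYGLNIIISREPVDSAATPANTCVNDFVFVAGSAAV",
    "GDCRSHTHIQEQEWSVWGMVDNVKIRFWAALVFLRDLNRDIATQPYRWFLSEIHIPAVKR",
    "LDVELKEATPIDRAGNLEISRVFGLDQGQPPSEELDSGPQFAADLL"
  )
  substrate <- substrate_protein(seq346, id = "pseudo_substrate_346")
  major <- tibble(
    p1 = c(41L, 82L, 107L, 25L, 11L, 54L, 126L, 142L, 160L, 270L, 282L, 300L, 326L),
    rate = c(
      0.04, 0.03, 0.02, # fast ungated surface sites
      0.010, 0.010, 0.008, 0.010, 0.006, 0.005, # gated second wave
      0.002, 0.0007, 0.00025, 0.0001 # late C-terminal block, steeply slowing
    ),
    gate = list(
      NULL, NULL, NULL,
      41L, 25L, 82L, 107L, 126L, 142L,
      142L, 270L, 282L, 300L
    )
  )
  minor <- tibble(
    p1 = c(33L, 70L, 95L, 117L, 134L, 150L, 170L, 260L, 290L, 310L, 335L),
    rate = 0.015,
    gate = list(NULL)
  )
  sites <- bind_rows(major, minor) |>
    mutate(rate = rate_scale * .data$rate)
  digestion_ground_truth(substrate, sites,
    n_molecules = n_molecules,
    detectable_length = detectable_length
  )
}

#' Ungated rate-ladder scenario for rate-rank recovery
#'
#' A validation scenario in which every site is ungated and intrinsic rates
#' form a geometric ladder, assigned in a "tent" along the chain (slowest
#' rates at the ends, fastest in the middle) so that chain-end sites -- which
#' have fewer observable partner products -- carry the least informative
#' rates. Sites are spaced 3 residues apart, giving each site several
#' potential partner products inside the detectable window; at an early
#' sampling time the number of detected products supporting a site then grades
#' with its rate, which is what makes rate-rank recovery from first-time-point
#' frequencies identifiable.
#'
#' @param n_molecules Ensemble size.
#' @param n_sites Number of sites (default 45).
#' @param rate_range Geometric ladder range in s^-1.
#' @param detectable_length Observable peptide length window.
#' @return A [digestion_ground_truth()].
#' @export
scenario_rate_ladder <- function(n_molecules = 10000, n_sites = 45,
                                 rate_range = c(2e-4, 4e-3),
                                 detectable_length = c(7, 25)) {
  base <- scenario_pseudo_anxa1(n_molecules = 1)
  positions <- seq(30L, by = 3L, length.out = n_sites)
  stopifnot(max(positions) < base$substrate$length)
  ladder <- exp(seq(log(rate_range[1]), log(rate_range[2]), length.out = n_sites))
  ord <- order(-abs(seq_len(n_sites) - (n_sites + 1) / 2)) # edges first
  rate <- numeric(n_sites)
  rate[ord] <- ladder
  digestion_ground_truth(
    base$substrate,
    tibble(p1 = positions, rate = rate, gate = list(NULL)),
    n_molecules = n_molecules,
    detectable_length = detectable_length
  )
}

#' Simulate a complete peptide-intensity experiment
#'
#' Runs the ensemble simulation, tallies observable products, adds
#' replicate-level log-normal noise with dropout, and assembles the long
#' peptide table the analysis functions consume (with peptide sequences,
#' identification scores, and protease-free control samples).
#'
#' @param ground_truth A [digestion_ground_truth()], e.g.
#'   [scenario_pseudo_anxa1()].
#' @param time_points Sampling times (seconds), ascending from 0. Default:
#'   the 11-point 0-3600 s folded-substrate design.
#' @param replicates Replicates per condition and time point (default 4).
#' @param sigma_lognormal,dropout_probability,intensity_scale,detection_limit
#'   See [add_noise()].
#' @param score_range Identification scores are drawn uniformly from this
#'   range, one per distinct peptide.
#' @param seed Integer seed controlling simulation, noise and scores.
#' @param protease_multiplier Global rate multiplier (protease concentration).
#' @return A list with `peptides` (long table: sequence, score, start, end,
#'   condition, replicate, time_s, intensity, is_control), `sample_map`,
#'   `simulation` (the event log) and `ground_truth`.
#' @export
simulate_peptide_table <- function(ground_truth,
                                   time_points = c(0, 15, 30, 60, 120, 180, 300,
                                                   600, 1200, 1800, 3600),
                                   replicates = 4,
                                   sigma_lognormal = 0.5,
                                   dropout_probability = 0.2,
                                   intensity_scale = 1e6,
                                   detection_limit = 0,
                                   score_range = c(30, 180),
                                   seed = 1L,
                                   protease_multiplier = 1) {
  sim <- simulate_digestion(ground_truth, time_points, seed = seed,
                            protease_multiplier = protease_multiplier)
  abund <- peptides_from_states(sim)
  samples <- add_noise(abund,
    replicates = replicates, sigma_lognormal = sigma_lognormal,
    dropout_probability = dropout_probability,
    intensity_scale = intensity_scale, detection_limit = detection_limit,
    seed = seed + 1L
  )
  sub <- ground_truth$substrate
  peps <- distinct(samples, .data$start, .data$end)
  peps$sequence <- substring(sub$sequence, peps$start, peps$end)
  withr::with_seed(seed + 2L, {
    peps$score <- round(runif(nrow(peps), score_range[1], score_range[2]), 2)
  })
  # full sample grid so non-detections are explicit zeros
  grid <- crossing(
    peps,
    condition = c("digest", "control"),
    replicate = seq_len(replicates),
    time_s = time_points
  )
  peptides <- grid |>
    left_join(samples,
      by = c("start", "end", "condition", "replicate", "time_s")
    ) |>
    mutate(
      intensity = replace_na(.data$intensity, 0),
      is_control = .data$condition == "control"
    ) |>
    select(
      "sequence", "score", "start", "end", "condition", "replicate",
      "time_s", "intensity", "is_control"
    ) |>
    arrange(.data$start, .data$end, .data$condition, .data$replicate, .data$time_s)
  sample_map <- peptides |>
    distinct(.data$condition, .data$replicate, .data$time_s) |>
    mutate(column = sprintf(
      "Intensity_%s_R%d_t%g", .data$condition, .data$replicate, .data$time_s
    )) |>
    select("column", "condition", "replicate", "time_s")
  list(
    peptides = peptides,
    sample_map = sample_map,
    simulation = sim,
    ground_truth = ground_truth
  )
}

#' Median per-site cleavage times from the simulation event log
#'
#' The "true" temporal order of sites under a scenario: the median time at
#' which each site fires across molecules (infinite if it never fires on a
#' molecule are excluded).
#'
#' @param simulation A [simulate_digestion()] result.
#' @return A tibble with `p1` and `median_time`, sorted by `median_time`.
#' @export
true_event_order <- function(simulation) {
  simulation$events |>
    group_by(.data$p1) |>
    summarise(median_time = median(.data$time), .groups = "drop") |>
    arrange(.data$median_time)
}
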
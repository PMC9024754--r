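# Synthetic derivative libraries with known ground truth.
#
# The generator emulates the statistical shape of a curated TMS-derivative
# RI library: base metabolites are small densely functionalised molecules
# (linear or branched C4-C8 skeletons carrying 2-4 hydroxyl / amino /
# carboxyl / thiol groups), every derivatization level from the free
# molecule up to the fully TMS-protected one is present, stereoisomer
# duplicates produce a Tanimoto = 1 peak, and distinct structures sharing a
# molecular formula create the near-isobaric collisions that drive the CI
# identification scenario.
#
# Base metabolites are drawn in structural families: a parent structure
# plus descendants generated by single structural edits (chain extension or
# shrinkage, moving a group, swapping a group type, toggling a methyl
# branch). The latent RI combines a fragment-additive contribution with a
# family random walk (each edit perturbs the residual), multiplied by a
# constant factor per TMS group. The family residual is the part of RI that
# fragment-additive reasoning cannot express, so a model can recover it
# only from structurally close training molecules -- which is what makes
# prediction error grow as training-set similarity falls.

.GEN_GROUPS <- data.frame(
  key = c("hydroxyl", "amino", "carboxyl", "thiol"),
  plain = c("O", "N", "C(=O)O", "S"),
  deriv = c("O[Si](C)(C)C", "N[Si](C)(C)C", "C(=O)O[Si](C)(C)C",
            "S[Si](C)(C)C"),
  weight = c(80, 60, 150, 90),
  extra_c = c(0L, 0L, 1L, 0L),
  stringsAsFactors = FALSE)

.GEN_BASE_OFFSET <- 400   # RI units
.GEN_CARBON_WEIGHT <- 55  # RI units per skeleton carbon
.GEN_BRANCH_WEIGHT <- 15  # RI units per methyl branch
.GEN_POSITION_SD <- 20    # RI units; positional-isomer contribution per site
.GEN_PAIR_SD <- 12        # RI units; proximity effect of a substituent pair
.GEN_STEREO_SD <- 12      # RI units; RI gap between stereoisomer stand-ins

# Deterministic pseudo-random position contribution of one substituent:
# where a group sits on the skeleton shifts RI (positional isomers elute
# apart). The effect depends on the depth from the nearer chain end,
# saturating at depth 3 -- interior positional isomers nearly co-elute,
# terminal vs internal substitution separates clearly. A fixed hash keeps
# it a pure function of structure.
position_effect <- function(grp, pos, nc) {
  if (length(pos) == 0L) return(0)
  z <- vapply(seq_along(pos), function(i) {
    d <- min(pos[i], nc + 1L - pos[i], 3L)
    u <- (.hash_int(sprintf("pe|%s|%d|%d", grp[i], d, nc), 9973L) - 0.5) / 9973
    qnorm(u)
  }, numeric(1))
  .GEN_POSITION_SD * sum(z)
}

# Proximity contribution of consecutive substituent pairs within three
# bonds of each other: close groups interact intramolecularly and shift RI;
# beyond that distance the interaction vanishes.
pair_effect <- function(grp, pos) {
  if (length(pos) < 2L) return(0)
  z <- vapply(seq_len(length(pos) - 1L), function(i) {
    d <- pos[i + 1L] - pos[i]
    if (d > 3L) return(0)
    u <- (.hash_int(sprintf("px|%s|%s|%d", grp[i], grp[i + 1L], d),
                    9973L) - 0.5) / 9973
    qnorm(u)
  }, numeric(1))
  .GEN_PAIR_SD * sum(z)
}

#' Parameters of the synthetic library generator
#'
#' @param n_base_metabolites Number of base metabolites (each emits one
#'   record per TMS level, so the library is roughly 4x larger).
#' @param rng_seed Integer seed; the generator is fully deterministic given
#'   the seed.
#' @param tms_factor Multiplicative RI increase per TMS group (1.055
#'   corresponds to the 5-6% step observed between TMS counterparts).
#' @param ri_noise_sd Measurement noise on the stored RI, RI units.
#' @param isomer_fraction Fraction of bases duplicated under a new id with
#'   an identical structure (stereoisomer stand-ins; Tanimoto = 1).
#' @param isobar_cluster_rate Fraction of bases that receive an engineered
#'   unrelated partner with the same molecular formula.
#' @param spectrum_peaks Maximum number of fragment peaks per pseudo-EI
#'   spectrum.
#' @param edit_sd Standard deviation of the family random-walk RI
#'   innovation per structural edit, RI units.
#' @param family_mean_children Mean number of edit-descendants per family.
#' @return A `generator_params` list.
#' @export
generator_params <- function(n_base_metabolites = 250L, rng_seed = 7L,
                             tms_factor = 1.055, ri_noise_sd = 10,
                             isomer_fraction = 0.1,
                             isobar_cluster_rate = 0.15,
                             spectrum_peaks = 12L, edit_sd = 20,
                             family_mean_children = 2.5) {
  stopifnot(n_base_metabolites >= 1L, tms_factor > 1, ri_noise_sd >= 0,
            isomer_fraction >= 0, isomer_fraction <= 1,
            isobar_cluster_rate >= 0, isobar_cluster_rate <= 1,
            spectrum_peaks >= 1L, edit_sd >= 0)
  structure(list(n_base_metabolites = as.integer(n_base_metabolites),
                 rng_seed = as.integer(rng_seed), tms_factor = tms_factor,
                 ri_noise_sd = ri_noise_sd,
                 isomer_fraction = isomer_fraction,
                 isobar_cluster_rate = isobar_cluster_rate,
                 spectrum_peaks = as.integer(spectrum_peaks),
                 edit_sd = edit_sd,
                 family_mean_children = family_mean_children),
            class = "generator_params")
}

# Render a structure (skeleton + sites) as SMILES with the first n_tms
# sites TMS-derivatized.
render_structure <- function(st, n_tms) {
  gi <- match(st$site_grp, .GEN_GROUPS$key)
  out <- character(0)
  for (i in seq_len(st$nc)) {
    out <- c(out, "C")
    if (i %in% st$branch) out <- c(out, "(C)")
    j <- which(st$site_pos == i)
    if (length(j)) {
      tok <- if (j <= n_tms) .GEN_GROUPS$deriv[gi[j]]
             else .GEN_GROUPS$plain[gi[j]]
      out <- c(out, "(", tok, ")")
    }
  }
  paste(out, collapse = "")
}

sample1 <- function(x) x[sample.int(length(x), 1L)]

rand_structure <- function() {
  nc <- sample(4:8, 1)
  k <- min(sample(2:4, 1), nc - 1L)
  nb <- rbinom(1, 1, 0.3)
  if (k + nb > nc) nb <- 0L
  pos <- sort(sample(nc, k + nb))
  list(nc = nc, branch = if (nb) pos[1] else integer(0),
       site_pos = tail(pos, k), site_grp = sample(.GEN_GROUPS$key, k,
                                                  replace = TRUE))
}

# One structural edit; NULL when no admissible edit is found.
mutate_structure <- function(st) {
  for (attempt in 1:30) {
    s <- st
    op <- sample(c("chain", "move", "swap", "branch"), 1L,
                 prob = c(0.35, 0.15, 0.3, 0.2))
    if (op == "chain") {
      nc2 <- s$nc + sample1(c(-1L, 1L))
      if (nc2 < 3L || nc2 > 10L ||
          max(c(s$site_pos, s$branch, 1L)) > nc2) next
      s$nc <- nc2
    } else if (op == "move") {
      free <- setdiff(seq_len(s$nc), c(s$site_pos, s$branch))
      if (!length(free)) next
      j <- sample.int(length(s$site_pos), 1L)
      s$site_pos[j] <- sample1(free)
      o <- order(s$site_pos)
      s$site_pos <- s$site_pos[o]; s$site_grp <- s$site_grp[o]
    } else if (op == "swap") {
      j <- sample.int(length(s$site_grp), 1L)
      s$site_grp[j] <- sample1(setdiff(.GEN_GROUPS$key, s$site_grp[j]))
    } else {
      if (length(s$branch)) s$branch <- integer(0)
      else {
        free <- setdiff(seq(2L, max(2L, s$nc - 1L)), s$site_pos)
        if (!length(free)) next
        s$branch <- sample1(free)
      }
    }
    if (!identical(s[c("nc", "branch", "site_pos", "site_grp")],
                   st[c("nc", "branch", "site_pos", "site_grp")]))
      return(s)
  }
  NULL
}

# Structure with the same molecular formula (at every TMS level) but a
# different skeleton: either the group positions are redrawn, or a methyl
# branch is traded against one chain carbon -- branched and linear isomers
# share a formula but elute apart.
isobar_partner <- function(st) {
  k <- length(st$site_pos)
  nb <- length(st$branch)
  for (attempt in 1:40) {
    trade <- runif(1) < 0.5
    if (trade && nb == 1L) {
      nc2 <- st$nc + 1L; nb2 <- 0L
    } else if (trade && nb == 0L && st$nc >= 5L && k <= st$nc - 2L) {
      nc2 <- st$nc - 1L; nb2 <- 1L
    } else {
      nc2 <- st$nc; nb2 <- nb
    }
    if (k + nb2 > nc2 || nc2 > 10L) next
    pos <- sort(sample(nc2, k + nb2))
    s <- list(nc = nc2, branch = if (nb2) pos[1] else integer(0),
              site_pos = tail(pos, k),
              site_grp = sample(st$site_grp))
    if (!identical(s, st[c("nc", "branch", "site_pos", "site_grp")]))
      return(s)
  }
  NULL
}

# Composition key: total carbons + sorted group multiset + TMS count fully
# determines the molecular formula within this fragment grammar.
composition_key <- function(st, n_tms) {
  total_c <- st$nc + length(st$branch) +
    sum(.GEN_GROUPS$extra_c[match(st$site_grp, .GEN_GROUPS$key)])
  paste0("C", total_c, "|", paste(sort(st$site_grp), collapse = "+"),
         "|TMS", n_tms)
}

#' Generate a synthetic derivative library with ground truth
#'
#' @param params A [generator_params()].
#' @return List with `library` (a validated [derivative_library()]) and
#'   `truth`, a data frame per record: `record_id`, `base_id`, `family_id`,
#'   `n_tms`, `latent_ri` (noise-free RI), `cluster_id` (formula-equivalence
#'   class; records sharing it are exact isobars) and the structural
#'   coordinates used by the spectrum generator.
#' @examples
#' \donttest{
#' gen <- generate_library(generator_params(n_base_metabolites = 20))
#' gen$library
#' }
#' @export
generate_library <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  if (params$n_base_metabolites < 1L) stop("need at least one base metabolite")
  with_seed(params$rng_seed, {
    bases <- list()
    fam <- 0L
    while (length(bases) < params$n_base_metabolites) {
      fam <- fam + 1L
      parent <- rand_structure()
      parent$res <- rnorm(1, 0, params$edit_sd)
      parent$family <- fam
      members <- list(parent)
      for (k in seq_len(rpois(1, params$family_mean_children))) {
        anc <- members[[sample.int(length(members), 1L)]]
        kid <- mutate_structure(anc)
        if (is.null(kid)) next
        kid$res <- anc$res + rnorm(1, 0, params$edit_sd)
        kid$family <- fam
        members <- c(members, list(kid))
      }
      bases <- c(bases, members)
    }
    bases <- bases[seq_len(params$n_base_metabolites)]

    recs <- list(); truth <- list(); bi <- 0L
    emit_base <- function(st, bi) {
      k <- length(st$site_pos)
      base_ri <- .GEN_BASE_OFFSET + .GEN_CARBON_WEIGHT * st$nc +
        .GEN_BRANCH_WEIGHT * length(st$branch) +
        sum(.GEN_GROUPS$weight[match(st$site_grp, .GEN_GROUPS$key)]) +
        position_effect(st$site_grp, st$site_pos, st$nc) +
        pair_effect(st$site_grp, st$site_pos) +
        st$res
      for (t in 0:k) {
        latent <- base_ri * params$tms_factor^t
        id <- sprintf("R%05d", length(recs) + 1L)
        recs[[length(recs) + 1L]] <<- data.frame(
          record_id = id, base_id = sprintf("B%04d", bi),
          name = sprintf("synthetic metabolite %04d (%dTMS)", bi, t),
          smiles = render_structure(st, t), n_tms = t,
          ri = latent + rnorm(1, 0, params$ri_noise_sd),
          stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <<- data.frame(
          record_id = id, base_id = sprintf("B%04d", bi),
          family_id = sprintf("F%04d", st$family), n_tms = t,
          latent_ri = latent, cluster_id = composition_key(st, t),
          nc = st$nc, n_branch = length(st$branch),
          branch_pos = if (length(st$branch)) st$branch else NA_integer_,
          groups = paste(st$site_grp, collapse = ","),
          positions = paste(st$site_pos, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
    for (b in bases) {
      bi <- bi + 1L
      emit_base(b, bi)
      twin <- runif(1) < params$isomer_fraction
      if (twin) {
        # stereoisomer stand-in: identical structure (Tanimoto = 1) under a
        # new id, with the small RI gap real stereoisomer pairs show
        b2 <- b
        b2$res <- b$res + rnorm(1, 0, .GEN_STEREO_SD)
        bi <- bi + 1L
        emit_base(b2, bi)
      }
      # isomer-rich compounds tend to sit in isobar-rich neighbourhoods, so
      # a twinned base always gets an unrelated same-formula partner
      if (twin || runif(1) < params$isobar_cluster_rate) {
        partner <- isobar_partner(b)
        if (!is.null(partner)) {
          partner$res <- rnorm(1, 0, 2 * params$edit_sd)
          partner$family <- b$family
          bi <- bi + 1L
          emit_base(partner, bi)
        }
      }
    }
    raw <- do.call(rbind, recs)
    truth <- do.call(rbind, truth)
    lib <- derivative_library(
      cbind(raw, monoisotopic_mass = NA_real_)[, c(.LIBRARY_COLUMNS)],
      provenance = sprintf("synthetic generator (seed %d, %d bases)",
                           params$rng_seed, params$n_base_metabolites))
    lib$monoisotopic_mass <- monoisotopic_mass(lib$smiles)
    list(library = lib, truth = truth)
  })
}

# Deterministic string hash onto 1..m (no RNG involvement).
.hash_int <- function(s, m) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 1048573
  (h %% m) + 1L
}

# Fragment tokens of a record, one per skeleton carbon describing its
# local environment (substituent and TMS state at the carbon and at its
# two neighbours), plus coarse whole-molecule marks. Shared local
# environments => shared peaks, so spectral similarity tracks the same
# structural overlap a circular fingerprint encodes.
record_tokens <- function(tr) {
  grp <- strsplit(tr$groups, ",")[[1]]
  pos <- as.integer(strsplit(tr$positions, ",")[[1]])
  lab <- rep("c", tr$nc)
  if (tr$n_branch > 0 && !is.na(tr$branch_pos)) lab[tr$branch_pos] <- "br"
  tms_flag <- seq_along(grp) <= tr$n_tms
  lab[pos] <- paste0(grp, ifelse(tms_flag, "*", ""))
  ctx <- c("end", lab, "end")
  envs <- sprintf("env:%s|%s|%s", lab, ctx[seq_len(tr$nc)],
                  ctx[seq_len(tr$nc) + 2L])
  c(sprintf("chain%d", tr$nc),
    sprintf("fg:%s", unique(grp)),
    envs)
}

#' Generate pseudo-EI spectra for a synthetic library
#'
#' Every structural fragment of a record is hashed to a deterministic m/z
#' bin between 50 and 500 Da with a lognormal intensity; records with at
#' least one TMS group additionally carry the characteristic TMS fragment
#' peaks at m/z 73 and 147. Shared fragments produce shared peaks, so
#' spectral similarity increases with structural similarity. The spectra are
#' statistical stand-ins, not simulations of electron-impact fragmentation.
#'
#' @param library The `library` element of [generate_library()].
#' @param truth The matching `truth` element.
#' @param params The [generator_params()] used for generation.
#' @return Named list of [ms_spectrum()] keyed by record id.
#' @export
generate_spectra <- function(library, truth, params = generator_params()) {
  stopifnot(nrow(library) == nrow(truth))
  out <- lapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    toks <- record_tokens(tr)
    mz <- vapply(toks, function(tk) 50 + .hash_int(tk, 451L) - 1L, numeric(1))
    u <- vapply(toks, function(tk)
      (.hash_int(paste0("int|", tk), 9973L) - 0.5) / 9973, numeric(1))
    base_lvl <- ifelse(startsWith(toks, "fg:"), 4.8,
                       ifelse(startsWith(toks, "chain"), 5.0, 5.5))
    int <- exp(base_lvl + qnorm(u))
    if (tr$n_tms > 0L) {
      mz <- c(mz, 73, 147)
      int <- c(int, 400, 200)
    }
    keep <- utils::head(order(int, decreasing = TRUE), params$spectrum_peaks)
    ms_spectrum(mz[keep], int[keep])
  })
  names(out) <- truth$record_id
  out
}
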
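# Simplified deconvoluted-mass search engine.
#
# A PFPS (one candidate precursor + all neutral fragment masses of the
# spectrum) is matched against every database protein, allowing either no
# unknown mass shift (when the precursor mass is within `zero_shift_tol_da`
# of the unmodified proteoform mass) or exactly one unknown mass shift equal
# to the precursor-minus-proteoform mass difference. The one-shift model
# localizes the shift after a split site: prefix (b-type) masses before the
# split are unshifted, those after it carry the shift, and suffix (y-type)
# masses mirror that. The score of a candidate is the number of matched
# experimental fragment masses; a binomial-null E-value makes scores
# comparable across proteins of different lengths.

# Zero-row PrSM tibble with the full column set.
empty_prsm_tibble <- function() {
  tibble(
    spectrum_id = character(), precursor_rank = integer(),
    feature_id = integer(), accession = character(), is_decoy = logical(),
    proteoform_mass = numeric(), shift_count = integer(),
    shift_da = numeric(), matched_count = integer(), nnmfm = numeric(),
    evalue = numeric(), matched_masses = list(), round = integer()
  )
}

# TRUE for every experimental mass within tol_ppm of some theoretical mass.
matches_any <- function(m, theo, tol_ppm) {
  if (!length(m)) return(logical(0))
  if (!length(theo)) return(rep(FALSE, length(m)))
  theo <- sort(theo)
  idx <- findInterval(m, theo)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(theo))
  (abs(m - theo[lo]) <= tol_ppm * 1e-6 * theo[lo]) |
    (abs(m - theo[hi]) <= tol_ppm * 1e-6 * theo[hi])
}

# Contiguous index range [jl, jr] of sorted vector `sorted` falling inside
# [lo, hi] (vectorized over lo/hi; jl > jr means empty). A relative nudge of
# 1e-12 keeps exact boundary values inclusive.
range_in_sorted <- function(lo, hi, sorted) {
  eps <- 1e-12
  lo_adj <- lo - abs(lo) * eps - eps
  hi_adj <- hi + abs(hi) * eps + eps
  list(
    jl = findInterval(lo_adj, sorted) + 1L,
    jr = findInterval(hi_adj, sorted)
  )
}

#' Match fragment masses without a mass shift
#'
#' Matches experimental neutral fragment masses against the theoretical
#' prefix (b-type) masses of a proteoform and their precursor-based suffix
#' (y-type) complements `precursor_mass - prefix`. A mass `m` matches a
#' theoretical mass `t` when `|m - t| <= tol_ppm * t * 1e-6`; each
#' experimental mass is counted at most once.
#'
#' @param frag_masses Sorted numeric experimental masses (Da).
#' @param form Output of [theoretical_prefix_masses()].
#' @param precursor_mass Precursor neutral mass (Da) used for suffixes.
#' @param tol_ppm Fragment tolerance in ppm.
#' @return The matched experimental masses (numeric, possibly empty).
#' @export
#' @examples
#' form <- theoretical_prefix_masses("AG")
#' match_zero_shift(c(71.03711), form, 146.06914, 15)
match_zero_shift <- function(frag_masses, form, precursor_mass, tol_ppm) {
  theo <- c(form$prefix_masses, precursor_mass - form$prefix_masses)
  theo <- theo[theo > 0]
  frag_masses[matches_any(frag_masses, theo, tol_ppm)]
}

#' Match fragment masses with one localized mass shift
#'
#' Places a single unknown mass shift after a split site `i` in
#' `0..(L-1)`: prefix masses with (1-based) index `<= i` are unshifted and
#' the rest are shifted by `shift_da`; suffix masses mirror this, so a
#' suffix over cleavage `j <= i` carries the shift
#' (`proteoform_mass + shift_da - prefix[j]`) and suffixes over `j > i` are
#' the unshifted complements (`proteoform_mass - prefix[j]`). The split
#' maximizing the number of matched experimental masses is returned
#' (smallest split on ties).
#'
#' @inheritParams match_zero_shift
#' @param shift_da The single unknown mass shift (Da).
#' @return A list: `matched` (experimental masses at the best split),
#'   `count` (their number) and `split` (best split index).
#' @export
match_one_shift <- function(frag_masses, form, shift_da, tol_ppm) {
  p <- form$prefix_masses
  np <- length(p)
  m0 <- form$proteoform_mass
  msh <- m0 + shift_da
  n <- length(frag_masses)
  if (!n || !np) {
    return(list(matched = numeric(0), count = 0L, split = 0L))
  }
  eps <- tol_ppm * 1e-6
  m <- frag_masses
  w_lo <- m / (1 + eps)
  w_hi <- m / (1 - eps)

  # j-ranges of prefix indices matched by each fragment under the 4 roles:
  a <- range_in_sorted(w_lo, w_hi, p)                  # unshifted prefix, j <= i
  b <- range_in_sorted(w_lo - shift_da, w_hi - shift_da, p)  # shifted prefix, j > i
  cc <- range_in_sorted(msh - w_hi, msh - w_lo, p)     # shifted suffix, j <= i
  d <- range_in_sorted(m0 - w_hi, m0 - w_lo, p)        # unshifted suffix, j > i

  # fragment matches split i on [0, u] (shifted-prefix / unshifted-suffix
  # roles need some j > i) and on [l, np] (roles needing some j <= i)
  u <- pmax(ifelse(b$jl <= b$jr, b$jr, 0L), ifelse(d$jl <= d$jr, d$jr, 0L)) - 1L
  l <- pmin(ifelse(a$jl <= a$jr, a$jl, np + 1L), ifelse(cc$jl <= cc$jr, cc$jl, np + 1L))

  diffs <- numeric(np + 2L)  # splits 0..np at offsets 1..np+1
  full <- u >= l - 1L
  add_lo <- !full & u >= 0L
  add_hi <- !full & l <= np
  if (any(full)) {
    diffs[1L] <- diffs[1L] + sum(full)
    diffs[np + 2L] <- diffs[np + 2L] - sum(full)
  }
  if (any(add_lo)) {
    diffs[1L] <- diffs[1L] + sum(add_lo)
    ends <- tabulate(u[add_lo] + 2L, nbins = np + 2L)
    diffs <- diffs - ends
  }
  if (any(add_hi)) {
    starts <- tabulate(l[add_hi] + 1L, nbins = np + 2L)
    diffs <- diffs + starts
    diffs[np + 2L] <- diffs[np + 2L] - sum(add_hi)
  }
  counts <- cumsum(diffs[seq_len(np + 1L)])
  best <- which.max(counts) - 1L

  theo <- c(p[seq_len(np) <= best],
            p[seq_len(np) > best] + shift_da,
            msh - p[seq_len(np) <= best],
            m0 - p[seq_len(np) > best])
  theo <- theo[theo > 0]
  matched <- m[matches_any(m, theo, tol_ppm)]
  list(matched = matched, count = length(matched), split = best)
}

#' Binomial-null E-value of a proteoform-spectrum match
#'
#' Models a random theoretical mass as hitting the spectrum with probability
#' `p = min(1, n_frag * 2 * tol_da_mean / mass_range)` and reports
#' `n_candidates * P[Binomial(n_theo, p) >= x]`, floored at 1e-300.
#'
#' @param x Matched fragment count (clamped to `n_theo` with a message).
#' @param n_frag Number of fragment masses in the searched spectrum.
#' @param n_theo Number of theoretical masses tested for the candidate.
#' @param tol_da_mean Mean matching tolerance in Da.
#' @param mass_range Mass range (Da) over which fragments may fall, > 0.
#' @param n_candidates Number of candidates scored in the search.
#' @return A positive E-value.
#' @export
#' @examples
#' binom_evalue(1, n_frag = 1, n_theo = 10, tol_da_mean = 0.005,
#'              mass_range = 1, n_candidates = 1)
binom_evalue <- function(x, n_frag, n_theo, tol_da_mean, mass_range,
                         n_candidates) {
  stopifnot(mass_range > 0, all(n_theo >= 0), all(x >= 0))
  if (any(x > n_theo)) {
    inform("matched count exceeds theoretical count; clamping")
    x <- pmin(x, n_theo)
  }
  p <- min(1, n_frag * 2 * tol_da_mean / mass_range)
  surv <- pbinom(x - 1, size = n_theo, prob = p, lower.tail = FALSE)
  pmax(n_candidates * surv, 1e-300)
}

#' Build a search index over a protein database
#'
#' Precomputes theoretical prefix masses and proteoform masses for every
#' protein so repeated [search_pfps()] calls do not recompute them.
#'
#' @param db Protein tibble (targets, or targets + decoys).
#' @return An object of class `search_index`.
#' @export
build_search_index <- function(db) {
  if (inherits(db, "search_index")) return(db)
  forms <- map(db$sequence, theoretical_prefix_masses)
  structure(
    list(
      accession = db$accession,
      is_decoy = db$is_decoy,
      prefix = map(forms, "prefix_masses"),
      mass = map_dbl(forms, "proteoform_mass"),
      n_theo = 2L * (nchar(db$sequence) - 1L)
    ),
    class = "search_index"
  )
}

#' Search one precursor-fragment paired spectrum
#'
#' Matches a PFPS against every database protein, trying a zero-shift match
#' when the precursor mass is within `zero_shift_tol_da` of the unmodified
#' proteoform mass and otherwise a one-shift match with shift equal to the
#' mass difference (when inside `[shift_min_da, shift_max_da]`). The best
#' candidate by matched-fragment count (ties: fewer shifts, then lower
#' E-value, then accession) is returned, or `NULL` when no candidate reaches
#' `min_match` matched masses.
#'
#' @param precursor One row of a precursor table (see [precursor_table()]).
#' @param frag_masses Sorted experimental neutral masses (Da).
#' @param db Protein tibble or prebuilt [build_search_index()] object.
#' @param cfg A [demux_config()].
#' @return A one-row PrSM tibble, or `NULL`.
#' @export
search_pfps <- function(precursor, frag_masses, db, cfg = demux_config()) {
  index <- build_search_index(db)
  pm <- precursor$neutral_mass[1]
  z <- precursor$rank[1] - 1L
  dm <- pm - index$mass
  zero_ok <- abs(dm) <= cfg$zero_shift_tol_da
  one_ok <- !zero_ok & dm >= cfg$shift_min_da & dm <= cfg$shift_max_da
  cand <- which(zero_ok | one_ok)
  if (!length(cand)) return(NULL)

  n_cand <- length(cand)
  xs <- integer(n_cand)
  ys <- integer(n_cand)
  shifts <- numeric(n_cand)
  matched <- vector("list", n_cand)
  for (k in seq_len(n_cand)) {
    i <- cand[k]
    form <- list(prefix_masses = index$prefix[[i]], proteoform_mass = index$mass[i])
    if (zero_ok[i]) {
      mm <- match_zero_shift(frag_masses, form, pm, cfg$frag_tol_ppm)
      shifts[k] <- 0
    } else {
      res <- match_one_shift(frag_masses, form, dm[i], cfg$frag_tol_ppm)
      mm <- res$matched
      ys[k] <- 1L
      shifts[k] <- dm[i]
    }
    matched[[k]] <- mm
    xs[k] <- length(mm)
  }
  if (max(xs) < cfg$min_match) return(NULL)

  tol_da_mean <- cfg$frag_tol_ppm * 1e-6 * pm / 2
  ev <- binom_evalue(xs, n_frag = length(frag_masses),
                     n_theo = index$n_theo[cand], tol_da_mean = tol_da_mean,
                     mass_range = pm, n_candidates = n_cand)
  # Ties: fewer shifts, lower E-value, then the accession stripped of the
  # decoy prefix (so decoy status never orders a tie between different
  # proteins); a target tied with its own decoy is decided by a
  # deterministic per-spectrum hash, keeping the null target/decoy
  # competition symmetric.
  acc <- index$accession[cand]
  acc_stripped <- sub(paste0("^", DECOY_PREFIX), "", acc)
  hash <- vapply(acc, function(a) {
    u <- utf8ToInt(a)
    sum(u * seq_along(u)) * 2654435761
  }, numeric(1))
  tie_hash <- (hash + round(pm * 1e5)) %% 1e9
  best <- order(-xs, ys, ev, acc_stripped, tie_hash)[1]
  i <- cand[best]
  tibble(
    spectrum_id = NA_character_,
    precursor_rank = z,
    feature_id = as.integer(precursor$feature_id[1]),
    accession = index$accession[i],
    is_decoy = index$is_decoy[i],
    proteoform_mass = pm,
    shift_count = ys[best],
    shift_da = shifts[best],
    matched_count = xs[best],
    nnmfm = xs[best] - ys[best] * cfg$delta - z * cfg$gamma,
    evalue = ev[best],
    matched_masses = list(matched[[best]]),
    round = NA_integer_
  )
}
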
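# Synthetic fingerprint populations.
#
# Real screening campaigns draw actives from a bioactivity database and
# decoys from a commercial catalogue. Offline, we emulate that structure:
# actives cluster into chemotypes (a shared scaffold = a template bit
# pattern plus per-compound bit-flip noise), while decoys are mostly
# background molecules with independent sparse bits, contaminated by a small
# fraction of "near-active" hard decoys sampled around the same templates
# with wider noise.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# fixed per-stream offsets so actives/decoys/splits draw from
# reproducible but non-overlapping streams of one master seed
.stream_offsets <- c(templates = 0L, actives = 101L, decoys = 211L,
                     split = 307L, trial = 401L, classifier = 503L)

stream_seed <- function(seed, stream) {
  off <- .stream_offsets[[stream]]
  as.integer((as.numeric(seed) + off) %% 2^31)
}

#' Build a chemotype model for synthetic fingerprint generation
#'
#' Samples `k` chemotype templates (one scaffold-like bit pattern each) and
#' bundles them with the noise parameters that govern active and decoy
#' generation. The defaults describe a moderately diverse target: 8
#' chemotypes over 166 bits at 30% template density, actives within 22%
#' bit-flip noise of their scaffold (a loose structural family, as in a
#' real bioactivity class), background decoys with sparse independent
#' bits, and 8% of decoys drawn as hard near-actives at 35% noise --
#' enough hard decoys that precision, not recall, limits a model screened
#' against a large library.
#'
#' @param k number of chemotypes (>= 1).
#' @param d fingerprint width in bits.
#' @param template_density per-bit Bernoulli rate for template bits, in
#'   (0, 1).
#' @param seed integer master seed; template sampling and all downstream
#'   draws derive per-stream seeds from it.
#' @param active_flip_prob per-bit flip probability for actives, in
#'   `[0, 0.5)`.
#' @param decoy_bit_probs per-bit Bernoulli rates for background decoys;
#'   either a scalar (recycled) or a length-`d` vector.
#' @param near_active_fraction fraction of decoys drawn as near-actives, in
#'   `[0, 1]`.
#' @param near_active_flip_prob per-bit flip probability for near-active
#'   decoys; must exceed `active_flip_prob` (they are harder than actives
#'   but not actives) and be at most 0.5.
#' @return a `chemotype_model` object.
#' @examples
#' model <- make_chemotypes(k = 2, d = 64, template_density = 0.25, seed = 1)
#' model
#' @export
make_chemotypes <- function(k, d = 166, template_density = 0.3, seed = 1,
                            active_flip_prob = 0.22, decoy_bit_probs = 0.15,
                            near_active_fraction = 0.08,
                            near_active_flip_prob = 0.35) {
  stopifnot(length(k) == 1, k >= 1, length(d) == 1, d >= 1)
  if (!(template_density > 0 && template_density < 1)) {
    stop("`template_density` must lie strictly between 0 and 1.", call. = FALSE)
  }
  if (!(active_flip_prob >= 0 && active_flip_prob < 0.5)) {
    stop("`active_flip_prob` must lie in [0, 0.5).", call. = FALSE)
  }
  if (!(near_active_fraction >= 0 && near_active_fraction <= 1)) {
    stop("`near_active_fraction` must lie in [0, 1].", call. = FALSE)
  }
  if (!(near_active_flip_prob > active_flip_prob && near_active_flip_prob <= 0.5)) {
    stop("`near_active_flip_prob` must lie in (active_flip_prob, 0.5].",
         call. = FALSE)
  }
  if (length(decoy_bit_probs) == 1) {
    decoy_bit_probs <- rep(decoy_bit_probs, d)
  }
  stopifnot(length(decoy_bit_probs) == d,
            all(decoy_bit_probs >= 0 & decoy_bit_probs <= 1))
  templates <- with_seed(stream_seed(seed, "templates"), {
    matrix(as.integer(stats::runif(k * d) < template_density),
           nrow = k, ncol = d)
  })
  if (any(rowSums(templates) == 0)) {
    # a scaffold with no bits set is chemically meaningless; force >= 1 bit
    for (i in which(rowSums(templates) == 0)) templates[i, 1] <- 1L
  }
  structure(
    list(templates = templates, k = as.integer(k), d = as.integer(d),
         template_density = template_density,
         active_flip_prob = active_flip_prob,
         decoy_bit_probs = decoy_bit_probs,
         near_active_fraction = near_active_fraction,
         near_active_flip_prob = near_active_flip_prob,
         seed = as.integer(seed)),
    class = "chemotype_model"
  )
}

#' @export
print.chemotype_model <- function(x, ...) {
  cat("<chemotype_model> ", x$k, " chemotypes x ", x$d, " bits; ",
      "active flip ", x$active_flip_prob, ", near-active fraction ",
      x$near_active_fraction, "\n", sep = "")
  invisible(x)
}

flip_bits <- function(template_rows, flip_prob) {
  n <- nrow(template_rows)
  d <- ncol(template_rows)
  flips <- matrix(stats::runif(n * d) < flip_prob, n, d)
  out <- template_rows
  out[flips] <- 1L - out[flips]
  out
}

#' Sample synthetic active compounds
#'
#' Each active is a uniformly chosen chemotype template with every bit
#' flipped independently with probability `active_flip_prob`. Compound ids
#' carry the chemotype index (`act00001_c3`) so that ground truth stays
#' attached to the fingerprints.
#'
#' @param model a `chemotype_model`.
#' @param n number of actives (>= 1).
#' @param seed integer seed for this draw (defaults to the model's actives
#'   stream).
#' @param kind fingerprint kind tag, see [fingerprint_matrix()].
#' @return a `fingerprint_matrix` of `n` actives.
#' @export
sample_actives <- function(model, n, seed = stream_seed(model$seed, "actives"),
                           kind = if (model$d == 166) "keyed-166" else "hashed-path") {
  stopifnot(inherits(model, "chemotype_model"), n >= 1)
  with_seed(seed, {
    chemotype <- sample.int(model$k, n, replace = TRUE)
    bits <- flip_bits(model$templates[chemotype, , drop = FALSE],
                      model$active_flip_prob)
    ids <- sprintf("act%05d_c%d", seq_len(n), chemotype)
    fingerprint_matrix(bits, ids, kind)
  })
}

#' Sample synthetic decoy compounds
#'
#' Each decoy is, independently with probability `near_active_fraction`, a
#' hard near-active (a random chemotype template with
#' `near_active_flip_prob` bit-flip noise) and otherwise a background
#' molecule with independent per-bit rates `decoy_bit_probs`. Rows are
#' shuffled deterministically under the seed so hard decoys are interleaved.
#' Near-active ids are tagged `dcy...._near`, background ids `dcy...._bg`.
#'
#' @inheritParams sample_actives
#' @return a `fingerprint_matrix` of `n` decoys.
#' @export
sample_decoys <- function(model, n, seed = stream_seed(model$seed, "decoys"),
                          kind = if (model$d == 166) "keyed-166" else "hashed-path") {
  stopifnot(inherits(model, "chemotype_model"), n >= 1)
  with_seed(seed, {
    near <- stats::runif(n) < model$near_active_fraction
    bits <- matrix(0L, n, model$d)
    n_bg <- sum(!near)
    if (n_bg > 0) {
      bits[!near, ] <- matrix(
        as.integer(stats::runif(n_bg * model$d) <
                     rep(model$decoy_bit_probs, each = n_bg)),
        nrow = n_bg, ncol = model$d
      )
    }
    if (any(near)) {
      chemotype <- sample.int(model$k, sum(near), replace = TRUE)
      bits[near, ] <- flip_bits(model$templates[chemotype, , drop = FALSE],
                                model$near_active_flip_prob)
    }
    ids <- sprintf("dcy%06d_%s", seq_len(n), ifelse(near, "near", "bg"))
    perm <- sample.int(n)
    fingerprint_matrix(bits[perm, , drop = FALSE], ids[perm], kind)
  })
}

#' Expected Tanimoto similarity between an active and its template
#'
#' Under the generative model, a bit contributes to the intersection with
#' probability `p (1 - f)` (template bit set and not flipped) and to the
#' union with probability `p + (1 - p) f`, where `p` is the template density
#' and `f` the flip probability. For wide fingerprints the Tanimoto ratio
#' concentrates around the ratio of these expectations,
#' `p (1 - f) / (p + (1 - p) f)` -- the closed form used as an oracle for
#' the generator.
#'
#' @param template_density template per-bit rate `p`.
#' @param flip_prob per-bit flip probability `f`.
#' @return expected Tanimoto similarity (large-width approximation).
#' @export
expected_template_tanimoto <- function(template_density, flip_prob) {
  p <- template_density
  f <- flip_prob
  p * (1 - f) / (p + (1 - p) * f)
}

#' Similarity density of a screening set around the actives
#'
#' The fraction of screening compounds whose maximum Tanimoto similarity to
#' any active reaches at least `s`. High values mean the library is crowded
#' with molecules that look like actives -- the property that makes a
#' screening problem hard and target-dependent.
#'
#' @param actives,screen `fingerprint_matrix` objects (or 0/1 matrices) of
#'   equal bit width.
#' @param s similarity threshold in `[0, 1]` (default 0.7, a conventional
#'   "same-series" Tanimoto level).
#' @return fraction of screening rows at or above the threshold.
#' @export
similarity_density <- function(actives, screen, s = 0.7) {
  stopifnot(length(s) == 1, s >= 0, s <= 1)
  best <- max_tanimoto(screen, actives)
  mean(best >= s)
}

#' Write a synthetic population with its ground-truth sidecar
#'
#' Writes the fingerprint table ([write_fingerprints()]) plus a label
#' sidecar (`compound_id,label,chemotype`) recovered from the generated ids.
#'
#' @param fp a `fingerprint_matrix` from [sample_actives()] or
#'   [sample_decoys()].
#' @param path fingerprint table path; the sidecar gets suffix
#'   `.labels.csv`.
#' @return tibble of the sidecar, invisibly.
#' @export
write_population <- function(fp, path) {
  stopifnot(inherits(fp, "fingerprint_matrix"))
  write_fingerprints(fp, path)
  is_active <- grepl("^act", fp$ids)
  chemotype <- ifelse(is_active, sub("^act\\d+_c", "", fp$ids), NA)
  sidecar <- tibble::tibble(
    compound_id = fp$ids,
    label = ifelse(is_active, "active", "inactive"),
    chemotype = suppressWarnings(as.integer(chemotype))
  )
  readr::write_csv(sidecar, paste0(path, ".labels.csv"), progress = FALSE)
  invisible(sidecar)
}
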
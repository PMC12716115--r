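# Deconvoluted spectra are kept in a tibble with one row per spectrum:
#   spectrum_id      character
#   iso_lo, iso_hi   isolation-window m/z bounds
#   precursors       list of tibbles (feature_id, neutral_mass, charge,
#                    avg_mz, intensity, rank), sorted by descending intensity
#   frag_masses      list of strictly increasing neutral masses (Da)
#   frag_intensities list of parallel non-negative abundances

#' Construct a precursor table
#'
#' Builds the per-spectrum candidate-precursor tibble, sorted by descending
#' isolation-window intensity and ranked 1 (highest) onwards.
#'
#' @param feature_id Integer proteoform-feature ids.
#' @param neutral_mass Neutral monoisotopic masses (Da), > 0.
#' @param charge Positive integer charge states.
#' @param avg_mz Average m/z of each feature.
#' @param intensity Isolation-window precursor intensities, >= 0.
#' @return A tibble with a `rank` column added.
#' @export
precursor_table <- function(feature_id, neutral_mass, charge, avg_mz, intensity) {
  tb <- tibble(
    feature_id = as.integer(feature_id),
    neutral_mass = as.numeric(neutral_mass),
    charge = as.integer(charge),
    avg_mz = as.numeric(avg_mz),
    intensity = as.numeric(intensity)
  )
  if (any(tb$neutral_mass <= 0)) abort("precursor neutral_mass must be > 0")
  if (any(tb$intensity < 0)) abort("precursor intensity must be >= 0")
  if (any(tb$charge < 1)) abort("precursor charge must be a positive integer")
  tb <- arrange(tb, desc(.data$intensity))
  tb$rank <- seq_len(nrow(tb))
  tb
}

#' Construct a deconvoluted-spectrum table
#'
#' Assembles and validates the tibble representation of deconvoluted MS/MS
#' spectra. Fragment masses are sorted ascending (duplicate masses collapse
#' to one entry keeping the highest intensity) and precursors are re-ranked
#' by descending intensity.
#'
#' @param spectrum_id Character ids, unique.
#' @param iso_lo,iso_hi Isolation-window m/z bounds, `iso_lo < iso_hi`.
#' @param precursors List of precursor tibbles (see [precursor_table()]),
#'   1 or 2 rows each.
#' @param frag_masses List of numeric neutral fragment masses (Da).
#' @param frag_intensities List of parallel intensities; defaults to 1 for
#'   every fragment.
#' @return A spectra tibble.
#' @export
deconv_spectra <- function(spectrum_id, iso_lo, iso_hi, precursors,
                           frag_masses, frag_intensities = NULL) {
  n <- length(spectrum_id)
  if (is.null(frag_intensities)) {
    frag_intensities <- map(frag_masses, ~ rep(1, length(.x)))
  }
  sp <- tibble(
    spectrum_id = as.character(spectrum_id),
    iso_lo = as.numeric(iso_lo),
    iso_hi = as.numeric(iso_hi),
    precursors = precursors,
    frag_masses = frag_masses,
    frag_intensities = frag_intensities
  )
  if (anyDuplicated(sp$spectrum_id)) abort("spectrum ids must be unique")
  if (any(sp$iso_lo >= sp$iso_hi)) abort("iso_lo must be < iso_hi")
  for (i in seq_len(n)) {
    pr <- sp$precursors[[i]]
    if (!nrow(pr) %in% c(1L, 2L)) {
      abort(paste0("spectrum ", sp$spectrum_id[i], ": need 1 or 2 precursors"))
    }
    sp$precursors[[i]] <- precursor_table(
      pr$feature_id, pr$neutral_mass, pr$charge, pr$avg_mz, pr$intensity
    )
    fm <- as.numeric(sp$frag_masses[[i]])
    fi <- as.numeric(sp$frag_intensities[[i]])
    if (length(fm) != length(fi)) {
      abort(paste0("spectrum ", sp$spectrum_id[i],
                   ": frag_masses and frag_intensities differ in length"))
    }
    if (any(fm <= 0)) abort(paste0("spectrum ", sp$spectrum_id[i], ": fragment masses must be > 0"))
    if (is.unsorted(fm, strictly = TRUE)) {
      ord <- order(fm)
      fm <- fm[ord]
      fi <- fi[ord]
      if (anyDuplicated(fm)) {
        # collapse exact duplicates, keeping the highest intensity
        grp <- factor(match(fm, unique(fm)), levels = seq_along(unique(fm)))
        fi <- as.numeric(tapply(fi, grp, max))
        fm <- unique(fm)
        inform(paste0("spectrum ", sp$spectrum_id[i],
                      ": duplicate fragment masses collapsed"))
      } else {
        inform(paste0("spectrum ", sp$spectrum_id[i],
                      ": fragment masses re-sorted"))
      }
      sp$frag_masses[[i]] <- fm
      sp$frag_intensities[[i]] <- fi
    } else {
      sp$frag_masses[[i]] <- fm
      sp$frag_intensities[[i]] <- fi
    }
  }
  sp
}

SPECTRUM_MANDATORY_KEYS <- c(
  "ID", "ISO_LO", "ISO_HI", "PRECURSOR_MASS_1", "PRECURSOR_CHARGE_1",
  "PRECURSOR_MZ_1", "PRECURSOR_INTENSITY_1", "PRECURSOR_FEATURE_1"
)

#' Read deconvoluted spectra
#'
#' Parses the plain-text deconvoluted-spectrum dialect: blocks delimited by
#' `BEGIN IONS` / `END IONS`, `KEY=VALUE` header lines (mandatory keys `ID`,
#' `ISO_LO`, `ISO_HI` and the `PRECURSOR_*_1` set; optional `*_2` set), then
#' one `mass<TAB>intensity` line per fragment.
#'
#' @param path Path to a spectrum file.
#' @return A spectra tibble (see [deconv_spectra()]).
#' @export
read_spectra <- function(path) {
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins)) {
    abort("malformed spectrum file: unbalanced BEGIN IONS/END IONS")
  }
  blocks <- map2(begins, ends, function(b, e) lines[(b + 1L):(e - 1L)])
  parsed <- imap(blocks, parse_spectrum_block)
  deconv_spectra(
    spectrum_id = map_chr(parsed, "spectrum_id"),
    iso_lo = map_dbl(parsed, "iso_lo"),
    iso_hi = map_dbl(parsed, "iso_hi"),
    precursors = map(parsed, "precursors"),
    frag_masses = map(parsed, "frag_masses"),
    frag_intensities = map(parsed, "frag_intensities")
  )
}

parse_spectrum_block <- function(block, block_index) {
  block <- block[nzchar(block)]
  is_header <- grepl("=", block, fixed = TRUE) & !grepl("\t", block, fixed = TRUE)
  headers <- block[is_header]
  keys <- sub("=.*$", "", headers)
  vals <- sub("^[^=]*=", "", headers)
  kv <- setNames(vals, keys)
  id <- if ("ID" %in% keys) kv[["ID"]] else paste0("<block ", block_index, ">")
  missing <- setdiff(SPECTRUM_MANDATORY_KEYS, keys)
  if (length(missing)) {
    abort(paste0("spectrum ", id, ": missing mandatory key(s): ",
                 paste(missing, collapse = ", ")))
  }
  has2 <- all(paste0(c("PRECURSOR_MASS_", "PRECURSOR_CHARGE_", "PRECURSOR_MZ_",
                       "PRECURSOR_INTENSITY_", "PRECURSOR_FEATURE_"), 2) %in% keys)
  idx <- if (has2) 1:2 else 1L
  precursors <- precursor_table(
    feature_id = as.integer(kv[paste0("PRECURSOR_FEATURE_", idx)]),
    neutral_mass = as.numeric(kv[paste0("PRECURSOR_MASS_", idx)]),
    charge = as.integer(kv[paste0("PRECURSOR_CHARGE_", idx)]),
    avg_mz = as.numeric(kv[paste0("PRECURSOR_MZ_", idx)]),
    intensity = as.numeric(kv[paste0("PRECURSOR_INTENSITY_", idx)])
  )
  frag_lines <- block[!is_header]
  if (length(frag_lines)) {
    parts <- strsplit(frag_lines, "\t", fixed = TRUE)
    frag_masses <- as.numeric(map_chr(parts, 1))
    frag_intensities <- as.numeric(map_chr(parts, 2))
  } else {
    frag_masses <- numeric()
    frag_intensities <- numeric()
  }
  list(
    spectrum_id = unname(kv[["ID"]]),
    iso_lo = as.numeric(kv[["ISO_LO"]]),
    iso_hi = as.numeric(kv[["ISO_HI"]]),
    precursors = precursors,
    frag_masses = frag_masses,
    frag_intensities = frag_intensities
  )
}

#' Write deconvoluted spectra
#'
#' Serializes a spectra tibble to the dialect read by [read_spectra()].
#' Masses and m/z values are printed with 5 decimals and intensities with 2,
#' so `write_spectra()` then [read_spectra()] is the identity at the printed
#' precision and re-serialization is byte-identical.
#'
#' @param spectra A spectra tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  blocks <- map(seq_len(nrow(spectra)), function(i) {
    pr <- spectra$precursors[[i]]
    hdr <- c(
      "BEGIN IONS",
      paste0("ID=", spectra$spectrum_id[i]),
      sprintf("ISO_LO=%.5f", spectra$iso_lo[i]),
      sprintf("ISO_HI=%.5f", spectra$iso_hi[i])
    )
    for (j in seq_len(nrow(pr))) {
      hdr <- c(hdr,
        sprintf("PRECURSOR_MASS_%d=%.5f", j, pr$neutral_mass[j]),
        sprintf("PRECURSOR_CHARGE_%d=%d", j, pr$charge[j]),
        sprintf("PRECURSOR_MZ_%d=%.5f", j, pr$avg_mz[j]),
        sprintf("PRECURSOR_INTENSITY_%d=%.2f", j, pr$intensity[j]),
        sprintf("PRECURSOR_FEATURE_%d=%d", j, pr$feature_id[j])
      )
    }
    frags <- sprintf("%.5f\t%.2f", spectra$frag_masses[[i]],
                     spectra$frag_intensities[[i]])
    c(hdr, frags, "END IONS", "")
  })
  writeLines(unlist(blocks), path)
  invisible(path)
}
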
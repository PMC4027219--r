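# Nearest-neighbor duplex melting thermodynamics with monovalent salt
# correction, dye-insertion (mismatch-like) penalties, melting-curve Tm
# extraction and delta-Tm summaries.

.nn_env <- new.env(parent = emptyenv())

# unified NN parameter set, pinned in inst/extdata/nn_unified_v1.csv
.nn_table <- function() {
  if (is.null(.nn_env$tab)) {
    path <- system.file("extdata", "nn_unified_v1.csv", package = "fretstab",
                        mustWork = TRUE)
    tab <- utils::read.csv(path, comment.char = "#")
    .nn_env$tab <- stats::setNames(
      lapply(seq_len(nrow(tab)), function(i) c(dh = tab$dh[i], ds = tab$ds[i])),
      tab$step)
  }
  .nn_env$tab
}

.revcomp <- function(seq) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1L]]), collapse = ""))
}

.check_seq <- function(seq, what) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop(what, " must be a non-empty sequence string")
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) stop(what, " contains non-ACGT characters")
  seq
}

#' Duplex specification for melting prediction
#'
#' @param top_strand,bottom_strand DNA sequences, both 5'->3' (A/C/G/T).
#'   `bottom_strand` defaults to the reverse complement of `top_strand`.
#' @param strand_conc_total Total single-strand concentration C_T in molar
#'   (default 5e-7, i.e. 500 nM).
#' @param na_molar Monovalent cation concentration (molar).
#' @param mg_molar Divalent (Mg2+) concentration (molar); folded into a
#'   monovalent equivalent inside [nn_tm()].
#' @param insertion_sites Integer positions (1-based, on the top strand)
#'   treated as internal chromophore insertions: the Watson-Crick pair at each
#'   site is replaced by a mismatch-like destabilization (see [nn_tm()]).
#' @return Object of class `duplex_spec`.
#' @export
duplex_spec <- function(top_strand, bottom_strand = NULL,
                        strand_conc_total = 5e-7, na_molar = 0.1,
                        mg_molar = 0, insertion_sites = integer(0)) {
  top_strand <- .check_seq(top_strand, "top_strand")
  if (is.null(bottom_strand)) bottom_strand <- .revcomp(top_strand)
  bottom_strand <- .check_seq(bottom_strand, "bottom_strand")
  stopifnot(strand_conc_total > 0, na_molar > 0, mg_molar >= 0)
  insertion_sites <- as.integer(insertion_sites)
  if (length(insertion_sites) &&
      (any(insertion_sites < 1L) || any(insertion_sites > nchar(top_strand))))
    stop("insertion_sites outside sequence bounds")
  if (nchar(top_strand) != nchar(bottom_strand))
    stop("strand length mismatch beyond declared insertion sites")
  # complementarity check, ignoring declared insertion sites
  comp <- strsplit(.revcomp(bottom_strand), "")[[1L]]
  topc <- strsplit(top_strand, "")[[1L]]
  bad <- which(topc != comp)
  if (length(setdiff(bad, insertion_sites)))
    stop("strands are not complementary outside declared insertion sites")
  structure(list(top_strand = top_strand, bottom_strand = bottom_strand,
                 strand_conc_total = strand_conc_total, na_molar = na_molar,
                 mg_molar = mg_molar, insertion_sites = insertion_sites),
            class = "duplex_spec")
}

# default insertion penalty (ddH kcal/mol, ddS cal/mol/K per site),
# calibrated once on a representative 34-bp duplex to give the ~0.5-0.7 C
# depression expected for replacing one Watson-Crick pair by a dye insertion
# treated as a dA-dG mismatch; see the methods vignette.
.default_insertion_penalty <- c(dh = 2.4, ds = 5.45)

#' Nearest-neighbor melting temperature
#'
#' Two-state bimolecular melting temperature from unified nearest-neighbor
#' enthalpy/entropy sums with per-terminal initiation terms:
#' `Tm(K) = 1000 * dH / (dS + R * ln(C_T / x))`, with `x = 4` for
#' non-self-complementary duplexes (`x = 1` when self-complementary, which
#' also adds the symmetry entropy correction). The monovalent salt correction
#' adds `0.368 * (N - 1) * ln([Na+_eq])` to the entropy, where `N` is the
#' duplex length; Mg2+ is folded into the monovalent equivalent as
#' `[Na+_eq] = [Na+] + 120 * sqrt([Mg2+ in mM]) / 1000` molar.
#'
#' Internal dye insertions (`insertion_sites`) are handled as a fixed
#' destabilization penalty per site added to dH/dS (default calibrated to a
#' single-mismatch-sized Tm depression); the result is flagged via
#' `insertion_penalty_applied`.
#'
#' @param duplex A [duplex_spec()].
#' @param insertion_penalty Named vector `c(dh=, ds=)` per insertion site
#'   (kcal/mol, cal/mol/K).
#' @return A `tm_result`: list with `tm_celsius`, `delta_h` (kcal/mol),
#'   `delta_s` (cal/mol/K, salt-corrected), `method = "nearest_neighbor"`,
#'   `insertion_penalty_applied`.
#' @export
nn_tm <- function(duplex, insertion_penalty = .default_insertion_penalty) {
  stopifnot(inherits(duplex, "duplex_spec"))
  nn <- .nn_table()
  seq <- duplex$top_strand
  n <- nchar(seq)
  if (n < 2L) stop("duplex must be at least 2 bp")
  chars <- strsplit(seq, "")[[1L]]
  steps <- paste0(chars[-n], chars[-1L])
  # complement-strand steps fold onto the tabulated ten
  canon <- function(s) if (!is.null(nn[[s]])) s else .revcomp(s)
  vals <- vapply(steps, function(s) nn[[canon(s)]], numeric(2L))
  dh <- sum(vals["dh", ])
  ds <- sum(vals["ds", ])
  for (b in chars[c(1L, n)]) {
    init <- if (b %in% c("G", "C")) nn[["init_GC"]] else nn[["init_AT"]]
    dh <- dh + init[["dh"]]; ds <- ds + init[["ds"]]
  }
  selfcomp <- identical(seq, .revcomp(seq)) && !length(duplex$insertion_sites)
  if (selfcomp) {
    dh <- dh + nn[["sym"]][["dh"]]; ds <- ds + nn[["sym"]][["ds"]]
  }
  n_ins <- length(duplex$insertion_sites)
  if (n_ins) {
    dh <- dh + n_ins * insertion_penalty[["dh"]]
    ds <- ds + n_ins * insertion_penalty[["ds"]]
  }
  na_eq <- duplex$na_molar + 120 * sqrt(duplex$mg_molar * 1000) / 1000
  ds_corr <- ds + 0.368 * (n - 1) * log(na_eq)
  x <- if (selfcomp) 1 else 4
  R <- 1.987
  tm_k <- 1000 * dh / (ds_corr + R * log(duplex$strand_conc_total / x))
  structure(list(tm_celsius = tm_k - 273.15, delta_h = dh, delta_s = ds_corr,
                 method = "nearest_neighbor",
                 insertion_penalty_applied = n_ins > 0L),
            class = "tm_result")
}

#' Extract Tm from a UV melting curve
#'
#' Tm is the temperature at the maximum of the smoothed first derivative
#' dA/dT of the absorbance melting curve, with parabolic sub-grid refinement
#' around the maximum.
#'
#' @param temps Temperature grid in degrees C, strictly increasing, >= 10
#'   points (e.g. 1 degree steps from 15 to 85).
#' @param absorbance A260 values on the same grid.
#' @param smooth_window Moving-average window (points, odd; default 5).
#' @return A `tm_result` with `method = "curve_derivative"`.
#' @export
extract_tm_from_curve <- function(temps, absorbance, smooth_window = 5L) {
  stopifnot(length(temps) == length(absorbance))
  if (length(temps) < 10L) stop("need at least 10 points")
  if (any(diff(temps) <= 0)) stop("temperature grid must be strictly increasing")
  if (smooth_window %% 2L == 0L) smooth_window <- smooth_window + 1L
  tmid <- (temps[-1L] + temps[-length(temps)]) / 2
  deriv <- diff(absorbance) / diff(temps)
  sm <- as.numeric(stats::filter(deriv, rep(1 / smooth_window, smooth_window),
                                 sides = 2L))
  ok <- which(!is.na(sm))
  if (!length(ok) || max(sm[ok]) <= 0 || diff(range(absorbance)) == 0)
    stop("no melting transition detected in curve")
  i <- ok[which.max(sm[ok])]
  tm <- tmid[i]
  # parabolic refinement through the three points around the maximum
  if (i > 1L && i < length(sm) && !is.na(sm[i - 1L]) && !is.na(sm[i + 1L])) {
    y1 <- sm[i - 1L]; y2 <- sm[i]; y3 <- sm[i + 1L]
    denom <- y1 - 2 * y2 + y3
    if (denom < 0) {
      delta <- 0.5 * (y1 - y3) / denom
      h <- tmid[i + 1L] - tmid[i]
      tm <- tmid[i] + delta * h
    }
  }
  structure(list(tm_celsius = tm, delta_h = NA_real_, delta_s = NA_real_,
                 method = "curve_derivative",
                 insertion_penalty_applied = FALSE),
            class = "tm_result")
}

#' @export
print.tm_result <- function(x, ...) {
  cat(sprintf("<tm_result> Tm = %.1f C (%s)%s\n", x$tm_celsius, x$method,
              if (isTRUE(x$insertion_penalty_applied))
                " [insertion penalty applied]" else ""))
  invisible(x)
}

#' Mean melting-temperature shifts relative to the unmodified duplex
#'
#' For each buffer condition, computes `dTm = Tm(labeled) - Tm(unmodified)`,
#' then averages over buffers per construct label and rounds to 0.1 degrees C.
#'
#' @param tm_table data.frame with columns `construct`, `buffer` and the Tm
#'   column named by `value_col`.
#' @param value_col Name of the Tm column (default `"tm_exp_c"`).
#' @param reference Construct label of the unmodified duplex (default
#'   `"unmodified"`).
#' @return data.frame with `construct`, `mean_delta_tm_c` (rounded to 0.1) and
#'   `n_buffers`, excluding the reference itself.
#' @export
delta_tm_summary <- function(tm_table, value_col = "tm_exp_c",
                             reference = "unmodified") {
  stopifnot(all(c("construct", "buffer", value_col) %in% names(tm_table)))
  ref <- tm_table[tm_table$construct == reference, , drop = FALSE]
  lab <- tm_table[tm_table$construct != reference, , drop = FALSE]
  if (nrow(ref) == 0L) stop("no rows for reference construct '", reference, "'")
  miss <- setdiff(unique(lab$buffer), unique(ref$buffer))
  if (length(miss))
    stop("missing unmodified entry for buffer(s): ", paste(miss, collapse = ", "))
  ref_tm <- stats::setNames(ref[[value_col]], ref$buffer)
  lab$delta <- lab[[value_col]] - ref_tm[lab$buffer]
  agg <- stats::aggregate(delta ~ construct, data = lab,
                          FUN = function(d) c(mean = mean(d), n = length(d)))
  data.frame(construct = agg$construct,
             mean_delta_tm_c = round(agg$delta[, "mean"], 1L),
             n_buffers = as.integer(agg$delta[, "n"]))
}

#' Measured duplex melting temperatures (in-repo fixture)
#'
#' Experimental and nearest-neighbor-predicted melting temperatures of the
#' replication-fork duplex constructs — unmodified, internally Cy3/Cy5-labeled
#' and externally Cy3/Cy5-labeled — at three ionic conditions (200/100/50 mM
#' NaCl with 12/6/3 mM MgCl2, 10 mM Tris pH 8.0).
#'
#' @return data.frame with columns `construct`, `buffer`, `na_mm`, `mg_mm`,
#'   `tm_exp_c`, `tm_theory_c`.
#' @export
duplex_tm_measured <- function() {
  path <- system.file("extdata", "duplex_tm_measured.csv",
                      package = "fretstab", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#")
}
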
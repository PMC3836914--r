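# Annealing-temperature calculation. One abstract contract (a registry of
# named methods sharing a single call signature) with four built-in methods:
# the Wallace rule and three nearest-neighbor parameterisations
# (Breslauer 1986, SantaLucia 1998 unified, Freier 1986). New methods can be
# registered without touching existing ones.

.R_GAS <- 1.987  # cal / (K mol)

# Nearest-neighbor stack tables: dh in kcal/mol, ds in cal/(K mol).
# Keys are the 10 unique dinucleotide stacks read 5'->3' on the top strand;
# the remaining 6 dinucleotides are covered by reverse-complement symmetry.
.NN_TABLES <- list(
  breslauer_nn = list(
    dh = c(AA = -9.1, AT = -8.6, TA = -6.0, CA = -5.8, GT = -6.5,
           CT = -7.8, GA = -5.6, CG = -11.9, GC = -11.1, GG = -11.0),
    ds = c(AA = -24.0, AT = -23.9, TA = -16.9, CA = -12.9, GT = -17.3,
           CT = -20.8, GA = -13.5, CG = -27.8, GC = -26.7, GG = -26.6),
    # initiation: entropy penalty depends on whether any G:C pair is present
    init = function(s) {
      if (grepl("[GC]", s)) list(dh = 0, ds = -16.8) else list(dh = 0, ds = -20.1)
    },
    sym_ds = -1.3
  ),
  santalucia_nn = list(
    dh = c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
           CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0),
    ds = c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9),
    # unified initiation: per-terminal terms, A:T vs G:C
    init = function(s) {
      ends <- c(substr(s, 1L, 1L), substr(s, nchar(s), nchar(s)))
      dh <- sum(ifelse(ends %in% c("A", "T"), 2.3, 0.1))
      ds <- sum(ifelse(ends %in% c("A", "T"), 4.1, -2.8))
      list(dh = dh, ds = ds)
    },
    sym_ds = -1.4
  ),
  # Freier et al. 1986 RNA nearest-neighbor parameters applied to the DNA
  # letters (T read as U), as an approximate long-oligo method.
  freier_nn = list(
    dh = c(AA = -6.6, AT = -5.7, TA = -8.1, CA = -10.5, GT = -10.2,
           CT = -7.6, GA = -13.3, CG = -8.0, GC = -14.2, GG = -12.2),
    ds = c(AA = -18.4, AT = -15.5, TA = -22.6, CA = -27.8, GT = -26.2,
           CT = -19.2, GA = -35.5, CG = -19.4, GC = -34.9, GG = -29.7),
    init = function(s) list(dh = 0, ds = -10.8),
    sym_ds = -1.4
  )
)

# map any dinucleotide to its table key via reverse-complement symmetry
.nn_stack_key <- function(dinuc) {
  if (dinuc %in% names(.NN_TABLES$santalucia_nn$dh)) return(dinuc)
  reverse_complement(dinuc)
}

.NN_KEY_MAP <- local({
  b <- c("A", "C", "G", "T")
  all16 <- as.vector(outer(b, b, paste0))
  stats::setNames(vapply(all16, .nn_stack_key, character(1)), all16)
})

is_self_complementary <- function(s) {
  identical(s, reverse_complement(s))
}

#' Annealing-temperature parameters
#'
#' @param oligo_concentration total oligo concentration in mol/L
#'   (default 5e-8, i.e. 50 nM).
#' @param monovalent_salt monovalent cation concentration in mol/L
#'   (default 0.05).
#' @param method one of the registered method names
#'   (\code{"wallace"}, \code{"breslauer_nn"}, \code{"santalucia_nn"},
#'   \code{"freier_nn"}). The default is the SantaLucia-parameterised
#'   nearest-neighbor calculation.
#' @return an object of class \code{tm_params}.
#' @export
tm_params <- function(oligo_concentration = 5e-8, monovalent_salt = 0.05,
                      method = "santalucia_nn") {
  stopifnot(is.numeric(oligo_concentration), oligo_concentration > 0,
            is.numeric(monovalent_salt), monovalent_salt > 0)
  if (!method %in% tm_methods()) {
    stop(sprintf("unknown Tm method '%s'; registered: %s",
                 method, paste(tm_methods(), collapse = ", ")), call. = FALSE)
  }
  structure(list(oligo_concentration = oligo_concentration,
                 monovalent_salt = monovalent_salt,
                 method = method),
            class = "tm_params")
}

#' Wallace-rule melting temperature
#'
#' Tm = 2 (A + T) + 4 (G + C), a rough rule of thumb for short oligos.
#'
#' @param s DNA string, non-empty and N-free.
#' @return temperature in degrees C.
#' @export
tm_wallace <- function(s) {
  b <- as_bases(s, "oligo")
  if (grepl("N", b, fixed = TRUE)) {
    stop("tm_wallace is undefined for sequences containing N", call. = FALSE)
  }
  codes <- encode_dna(b)
  at <- sum(codes == 1L | codes == 4L)
  gc <- sum(codes == 2L | codes == 3L)
  2 * at + 4 * gc
}

#' Nearest-neighbor melting temperature
#'
#' Sums enthalpy/entropy contributions over adjacent dinucleotide stacks from
#' the parameter table named by \code{method}, adds that table's published
#' initiation terms, and evaluates
#' \deqn{T_m = \Delta H / (\Delta S + R \ln(C_T / x)) - 273.15 +
#'       16.6 \log_{10}[\mathrm{Na}^+]}
#' with R = 1.987 cal/(K mol). The symmetry factor x is 4 for a
#' non-self-complementary duplex and 1 (plus the table's symmetry entropy
#' correction) for a self-complementary one.
#'
#' @param s DNA string of length >= 2, N-free.
#' @param method \code{"breslauer_nn"}, \code{"santalucia_nn"} or
#'   \code{"freier_nn"}.
#' @param oligo_concentration total oligo concentration, mol/L.
#' @param monovalent_salt monovalent cation concentration, mol/L.
#' @param symmetry_factor override the duplex symmetry factor x (rarely
#'   needed; default NULL picks 4 or 1 automatically).
#' @return temperature in degrees C.
#' @export
tm_nearest_neighbor <- function(s, method = "santalucia_nn",
                                oligo_concentration = 5e-8,
                                monovalent_salt = 0.05,
                                symmetry_factor = NULL) {
  b <- as_bases(s, "oligo")
  if (grepl("N", b, fixed = TRUE)) {
    stop("nearest-neighbor Tm is undefined for sequences containing N", call. = FALSE)
  }
  if (nchar(b) < 2L) {
    stop("nearest-neighbor Tm needs at least one dinucleotide stack (length >= 2)",
         call. = FALSE)
  }
  tab <- .NN_TABLES[[method]]
  if (is.null(tab)) {
    stop(sprintf("unknown nearest-neighbor method '%s'", method), call. = FALSE)
  }
  n <- nchar(b)
  stacks <- .NN_KEY_MAP[substring(b, seq_len(n - 1L), seq_len(n - 1L) + 1L)]
  dh <- sum(tab$dh[stacks])
  ds <- sum(tab$ds[stacks])
  init <- tab$init(b)
  dh <- dh + init$dh
  ds <- ds + init$ds
  selfcomp <- is_self_complementary(b)
  if (selfcomp) ds <- ds + tab$sym_ds
  x <- if (!is.null(symmetry_factor)) symmetry_factor else if (selfcomp) 1 else 4
  tm <- dh * 1000 / (ds + .R_GAS * log(oligo_concentration / x)) - 273.15
  tm + 16.6 * log10(monovalent_salt)
}

# ---- method registry -------------------------------------------------------
# Every method is a function(s, params) -> temperature in degrees C, so
# callers can swap methods (or add new ones) without code changes.

.tm_registry <- new.env(parent = emptyenv())

#' Register an annealing-temperature method
#'
#' Adds a named method to the registry behind \code{melting_temperature}.
#' Registering a new method never alters existing ones; re-registering a
#' built-in name is refused.
#'
#' @param name method name (used in \code{tm_params} and the CLI
#'   \code{--tm-method} flag).
#' @param fun function(s, params) returning a temperature in degrees C.
#' @param overwrite allow replacing an existing non-built-in method.
#' @return \code{name}, invisibly.
#' @export
register_tm_method <- function(name, fun, overwrite = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  builtin <- c("wallace", "breslauer_nn", "santalucia_nn", "freier_nn")
  if (name %in% builtin && exists(name, envir = .tm_registry)) {
    stop(sprintf("'%s' is a built-in method and cannot be replaced", name),
         call. = FALSE)
  }
  if (exists(name, envir = .tm_registry) && !overwrite) {
    stop(sprintf("Tm method '%s' already registered", name), call. = FALSE)
  }
  assign(name, fun, envir = .tm_registry)
  invisible(name)
}

#' Registered annealing-temperature method names
#' @return character vector of method names.
#' @export
tm_methods <- function() {
  sort(ls(.tm_registry))
}

#' Melting temperature via a registered method
#'
#' The single entry point used throughout the package: dispatches on
#' \code{params$method}.
#'
#' @param s DNA string or \code{dna_seq}.
#' @param params a \code{tm_params} object.
#' @return temperature in degrees C.
#' @export
melting_temperature <- function(s, params = tm_params()) {
  stopifnot(inherits(params, "tm_params"))
  fun <- get0(params$method, envir = .tm_registry)
  if (is.null(fun)) {
    stop(sprintf("unknown Tm method '%s'", params$method), call. = FALSE)
  }
  fun(as_bases(s, "oligo"), params)
}

# built-in registrations (run at load time via a file-level local())
local({
  assign("wallace", function(s, params) tm_wallace(s), envir = .tm_registry)
  for (m in c("breslauer_nn", "santalucia_nn", "freier_nn")) {
    local({
      mm <- m
      assign(mm, function(s, params) {
        tm_nearest_neighbor(s, method = mm,
                            oligo_concentration = params$oligo_concentration,
                            monovalent_salt = params$monovalent_salt)
      }, envir = .tm_registry)
    })
  }
})
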
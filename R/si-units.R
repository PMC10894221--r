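#' Parse an SI-suffixed quantity
#'
#' Configuration files may give component values as suffixed strings
#' (`"8.2k"`, `"100p"`, `"10n"`). Internally everything is strict SI
#' (volts, ohms, farads, seconds); this parser converts at load time.
#'
#' @param x A number (returned as-is) or a string with an optional SI suffix
#'   among `f, p, n, u, m, k, M, G`.
#' @return A double in base SI units.
#' @examples
#' si_parse("8.2k")   # 8200
#' si_parse("100p")   # 1e-10
#' @export
si_parse <- function(x) {
  if (is.numeric(x)) return(as.double(x))
  stopifnot(is.character(x))
  vapply(x, function(s) {
    s <- trimws(s)
    m <- regmatches(s, regexec("^([0-9.eE+-]+)\\s*([fpnumkMG]?)$", s))[[1]]
    if (length(m) == 0) osc_abort("parse", paste0("cannot parse quantity: '", s, "'"))
    mult <- c(f = 1e-15, p = 1e-12, n = 1e-9, u = 1e-6, m = 1e-3,
              k = 1e3, M = 1e6, G = 1e9)
    num <- as.double(m[2])
    if (is.na(num)) osc_abort("parse", paste0("cannot parse quantity: '", s, "'"))
    if (m[3] == "") num else num * mult[[m[3]]]
  }, numeric(1), USE.NAMES = FALSE)
}
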
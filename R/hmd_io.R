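#' Read a Human Mortality Database period 1x1 life-table file
#'
#' Parses the HMD period life-table text layout: free-text header lines, a
#' column-header line (`Year Age mx qx ax lx dx Lx Tx ex`), then one
#' whitespace-delimited row per year and age. The open age group is written
#' as `110+` (any trailing `+` is accepted); a bare `.` marks a missing
#' value. Each year's block must cover contiguous ages starting at 0.
#'
#' @param source path to a file, a connection, or a character vector of
#'   lines.
#' @param dialect file dialect; only `"period_1x1"` is supported.
#' @return A named list of [new_lifetable()] objects, one per year, names
#'   being the years.
#' @examples
#' lt <- build_lifetable_from_mx(c(0.01, 0.01, 0.5), year = 2000)
#' f <- tempfile()
#' write_hmd_lifetable(list(lt), f)
#' read_hmd_lifetable(f)[["2000"]]
#' @export
read_hmd_lifetable <- function(source, dialect = "period_1x1") {
  dialect <- match.arg(dialect, "period_1x1")
  lines <- if (is.character(source) && length(source) > 1) source
           else readLines(source)
  cols <- c("Year", "Age", "mx", "qx", "ax", "lx", "dx", "Lx", "Tx", "ex")
  hdr <- grep("^\\s*Year\\s+Age\\b", lines)
  if (!length(hdr)) stop("schema error: no 'Year Age ...' header line found")
  hdr <- hdr[1]
  hdr_tokens <- strsplit(trimws(lines[hdr]), "\\s+")[[1]]
  missing_cols <- setdiff(cols, hdr_tokens)
  if (length(missing_cols))
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  body_idx <- seq(hdr + 1L, length(lines))
  body_idx <- body_idx[nzchar(trimws(lines[body_idx]))]
  if (!length(body_idx)) stop("schema error: no data rows")

  toks <- strsplit(trimws(lines[body_idx]), "\\s+")
  nt <- lengths(toks)
  if (any(nt != length(hdr_tokens)))
    stop("parse error at line ", body_idx[which(nt != length(hdr_tokens))[1]],
         ": wrong number of fields")
  m <- matrix(unlist(toks), ncol = length(hdr_tokens), byrow = TRUE,
              dimnames = list(NULL, hdr_tokens))[, cols, drop = FALSE]

  age_tok <- m[, "Age"]
  open_flag <- grepl("\\+$", age_tok)
  age_num <- suppressWarnings(as.integer(sub("\\+$", "", age_tok)))
  if (anyNA(age_num))
    stop("parse error at line ", body_idx[which(is.na(age_num))[1]],
         ": malformed age token '", age_tok[which(is.na(age_num))[1]], "'")
  num <- function(col) {
    v <- m[, col]
    v[v == "."] <- NA
    as.numeric(v)
  }
  year <- as.integer(m[, "Year"])

  out <- list()
  for (yr in unique(year)) {
    i <- which(year == yr)
    o <- order(age_num[i])
    i <- i[o]
    ages <- age_num[i]
    if (!all(ages == seq(0L, length(ages) - 1L)))
      stop("parse error: ages for year ", yr,
           " are not contiguous from 0")
    if (!open_flag[i[length(i)]] || any(open_flag[i[-length(i)]]))
      stop("parse error: year ", yr,
           " must end with a single open age group ('110+')")
    lt <- new_lifetable(
      ages = ages, mx = num("mx")[i], qx = num("qx")[i], ax = num("ax")[i],
      lx = num("lx")[i], dx = num("dx")[i], Lx = num("Lx")[i],
      Tx = num("Tx")[i], ex = num("ex")[i], year = yr)
    out[[as.character(yr)]] <- lt
  }
  out
}

#' Write life tables in the HMD period 1x1 text layout
#'
#' Inverse of [read_hmd_lifetable()]. Numeric fields are written at full
#' double precision (`%.10g`) rather than HMD's printed rounding, so a
#' write/read round trip reproduces the input fields exactly; files rounded
#' HMD-style are read just the same.
#'
#' @param tables a `lifetable` or list of them (each needs a `year`).
#' @param path output file path or connection.
#' @param title free-text first header line.
#' @return `path`, invisibly.
#' @export
write_hmd_lifetable <- function(tables, path,
                                title = "Synthetic, Life tables (period 1x1)") {
  if (inherits(tables, "lifetable")) tables <- list(tables)
  fmt <- function(v) ifelse(is.na(v), ".", sprintf("%.10g", v))
  lines <- c(title, "",
             sprintf("%6s %6s %10s %10s %6s %10s %10s %10s %12s %8s",
                     "Year", "Age", "mx", "qx", "ax", "lx", "dx", "Lx",
                     "Tx", "ex"))
  for (lt in tables) {
    n <- length(lt$ages)
    age_tok <- c(as.character(lt$ages[-n]), paste0(lt$ages[n], "+"))
    lines <- c(lines, sprintf(
      "%6d %6s %10s %10s %6s %10s %10s %10s %12s %8s",
      lt$year, age_tok, fmt(lt$mx), fmt(lt$qx), fmt(lt$ax), fmt(lt$lx),
      fmt(lt$dx), fmt(lt$Lx), fmt(lt$Tx), fmt(lt$ex)))
  }
  writeLines(lines, path)
  invisible(path)
}
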
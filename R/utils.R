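#' @keywords internal
"_PACKAGE"

# ---- conditions -------------------------------------------------------------

stop_lungsop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "lungsop_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

warn_lungsop <- function(class, msg, ...) {
  warning(structure(
    class = c(class, "lungsop_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

# ---- numerics ---------------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

fro_norm <- function(m) sqrt(sum(m * m))

#' Round half-up to a given number of decimals
#'
#' Base `round()` rounds half to even; parameter tables in the field
#' conventionally round half up (e.g. 25.55 -> 25.6).
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# Evaluate expr with a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())
    ), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a stream of per-item seeds from a master seed; stays below 2^31.
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) %% 499979) * 4093 + (index %% 4093) + 1)
}

stopifnot_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) {
    stop_lungsop("lungsop_nonfinite", sprintf("%s contains non-finite values", what))
  }
}

# ---- image helpers ----------------------------------------------------------

#' Bilinear resize of a grayscale image matrix
#'
#' @param img numeric matrix `[H, W]`
#' @param out_h,out_w output dimensions
#' @return numeric matrix `[out_h, out_w]`
#' @export
resize_bilinear <- function(img, out_h, out_w) {
  stopifnot(is.matrix(img), out_h >= 1, out_w >= 1)
  h <- nrow(img); w <- ncol(img)
  # align-corners = FALSE convention (pixel centers)
  ys <- (seq_len(out_h) - 0.5) * h / out_h + 0.5
  xs <- (seq_len(out_w) - 0.5) * w / out_w + 0.5
  interp_bilinear(img, ys, xs, outer_grid = TRUE)
}

# Sample img at (ys, xs); either the outer grid of two coordinate vectors or
# paired coordinates of equal length. Out-of-range coordinates clamp to edge.
interp_bilinear <- function(img, ys, xs, outer_grid = FALSE, fill = NULL) {
  h <- nrow(img); w <- ncol(img)
  if (outer_grid) {
    yy <- rep(ys, times = length(xs))
    xx <- rep(xs, each = length(ys))
  } else {
    yy <- ys; xx <- xs
  }
  oob <- NULL
  if (!is.null(fill)) {
    oob <- yy < 0.5 | yy > h + 0.5 | xx < 0.5 | xx > w + 0.5
  }
  yy <- pmin(pmax(yy, 1), h)
  xx <- pmin(pmax(xx, 1), w)
  y0 <- pmin(floor(yy), h - 1L); y0 <- pmax(y0, 1L)
  x0 <- pmin(floor(xx), w - 1L); x0 <- pmax(x0, 1L)
  fy <- yy - y0; fx <- xx - x0
  i00 <- cbind(y0, x0); i10 <- cbind(y0 + 1, x0)
  i01 <- cbind(y0, x0 + 1); i11 <- cbind(y0 + 1, x0 + 1)
  v <- img[i00] * (1 - fy) * (1 - fx) + img[i10] * fy * (1 - fx) +
    img[i01] * (1 - fy) * fx + img[i11] * fy * fx
  if (!is.null(oob)) v[oob] <- fill
  if (outer_grid) matrix(v, length(ys), length(xs)) else v
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# ---- plain-text PNM (PGM/PPM) readers/writers -------------------------------
# Used for text-only fixtures; PNG is handled by the png package.

read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2)
  if (!magic %in% c("P2", "P5")) {
    stop_lungsop("lungsop_unreadable_file", sprintf("unsupported PNM magic '%s'", magic))
  }
  toks <- character(0)
  buf <- character(0)
  # read header tokens (width, height, maxval), skipping comments
  while (length(toks) < 3) {
    ch <- readChar(con, 1)
    if (length(ch) == 0) stop_lungsop("lungsop_unreadable_file", "truncated PNM header")
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1)
        if (length(ch) == 0 || ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (length(buf)) {
        toks <- c(toks, paste(buf, collapse = ""))
        buf <- character(0)
      }
    } else {
      buf <- c(buf, ch)
    }
  }
  dims <- as.integer(toks[1:2])
  maxval <- as.integer(toks[3])
  n <- dims[1] * dims[2]
  if (magic == "P5") {
    vals <- as.integer(readBin(con, "integer", n = n, size = 1, signed = FALSE))
  } else {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  }
  # PNM is row-major (rows of the image in file order)
  t(matrix(vals / maxval, nrow = dims[1], ncol = dims[2]))
}

write_pgm <- function(img, path, ascii = TRUE) {
  stopifnot(is.matrix(img))
  vals <- round(clip01(img) * 255)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con)
    write(t(vals), file = con, ncolumns = ncol(img))
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", ncol(img), nrow(img)), con, eos = NULL)
    writeBin(as.integer(t(vals)), con, size = 1)
  }
  invisible(path)
}
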
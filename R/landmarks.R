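#' A single specimen's landmark configuration
#'
#' Holds a k x 3 coordinate matrix (mm) with a per-landmark missing mask, a
#' specimen identifier, and an optional population/group label.
#'
#' @param coords k x 3 numeric matrix.
#' @param specimen_id character scalar.
#' @param missing logical vector of length k; `TRUE` marks unobserved
#'   landmarks (their coordinate rows are ignored and may be `NA`).
#' @param group optional population label.
#' @return object of class `landmark_config`.
#' @export
landmark_config <- function(coords, specimen_id = "specimen", missing = NULL,
                            group = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must be a k x 3 matrix")
  k <- nrow(coords)
  if (is.null(missing)) missing <- rowSums(is.na(coords)) > 0
  stopifnot(length(missing) == k)
  if (any(!is.finite(coords[!missing, , drop = FALSE])))
    stop("coords must be finite wherever not missing")
  structure(list(specimen_id = as.character(specimen_id), coords = coords,
                 missing = as.logical(missing), group = group),
            class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat("Landmark configuration '", x$specimen_id, "': ",
      nrow(x$coords), " landmarks", sep = "")
  if (any(x$missing)) cat(" (", sum(x$missing), " missing)", sep = "")
  if (!is.null(x$group)) cat(", group =", x$group)
  cat("\n")
  invisible(x)
}

as_config <- function(x, id = "specimen", group = NULL) {
  if (inherits(x, "landmark_config")) x else landmark_config(x, id, group = group)
}

#' Read/write landmark coordinates as CSV
#'
#' One row per landmark with columns `id, x, y, z, missing`; coordinates in
#' mm. Missing landmarks carry `missing = 1` (coordinates may be empty/NA).
#'
#' @param path file path.
#' @param specimen_id,group passed to [landmark_config()].
#' @return `read_landmarks_csv` returns a [landmark_config].
#' @export
read_landmarks_csv <- function(path, specimen_id = basename(path), group = NULL) {
  d <- utils::read.csv(path)
  need <- c("x", "y", "z")
  if (!all(need %in% names(d))) stop("CSV needs columns x,y,z")
  miss <- if ("missing" %in% names(d)) as.logical(d$missing) else rep(FALSE, nrow(d))
  miss <- miss | is.na(d$x) | is.na(d$y) | is.na(d$z)
  landmark_config(cbind(d$x, d$y, d$z), specimen_id, missing = miss, group = group)
}

#' @rdname read_landmarks_csv
#' @param config a [landmark_config].
#' @export
write_landmarks_csv <- function(config, path) {
  d <- data.frame(id = seq_len(nrow(config$coords)),
                  x = config$coords[, 1], y = config$coords[, 2],
                  z = config$coords[, 3],
                  missing = as.integer(config$missing))
  d[d$missing == 1, c("x", "y", "z")] <- NA
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read/write landmark files in the classic TPS format
#'
#' Reads `LM3=` blocks (one per specimen) with one `x y z` triple per line,
#' and optional `ID=` lines. The conventional missing-value sentinel
#' `9999 9999 9999` (or `NA`s) marks missing landmarks.
#'
#' @param path file path.
#' @return `read_tps` returns a list of [landmark_config] objects.
#' @export
read_tps <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  starts <- grep("^LM3\\s*=", lines, ignore.case = TRUE)
  if (!length(starts)) stop("no LM3= blocks found in ", path)
  out <- list()
  for (b in seq_along(starts)) {
    i <- starts[b]
    k <- as.integer(sub("^LM3\\s*=\\s*", "", lines[i], ignore.case = TRUE))
    block <- lines[(i + 1):(i + k)]
    m <- do.call(rbind, lapply(strsplit(block, "\\s+"), function(v)
      suppressWarnings(as.numeric(v[1:3]))))
    end <- if (b < length(starts)) starts[b + 1] - 1 else length(lines)
    idline <- grep("^ID\\s*=", lines[(i + k):min(end, length(lines))],
                   ignore.case = TRUE, value = TRUE)
    id <- if (length(idline)) sub("^ID\\s*=\\s*", "", idline[1], ignore.case = TRUE)
          else paste0("specimen_", b)
    miss <- apply(m, 1, function(r) any(is.na(r)) || all(r == 9999))
    m[miss, ] <- NA
    out[[b]] <- landmark_config(m, id, missing = miss)
  }
  out
}

#' @rdname read_tps
#' @param configs list of [landmark_config] objects.
#' @export
write_tps <- function(configs, path) {
  if (inherits(configs, "landmark_config")) configs <- list(configs)
  con <- file(path, "w")
  on.exit(close(con))
  for (cfg in configs) {
    writeLines(paste0("LM3=", nrow(cfg$coords)), con)
    m <- cfg$coords
    m[cfg$missing, ] <- 9999
    writeLines(apply(m, 1, function(r) paste(format(r, trim = TRUE), collapse = " ")), con)
    writeLines(paste0("ID=", cfg$specimen_id), con)
  }
  invisible(path)
}
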
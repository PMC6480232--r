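#' Define a finite line source
#'
#' @param id character id.
#' @param x1,y1,x2,y2 endpoints, projected meters.
#' @param category source-category label (emissions are fitted per category).
#' @param h release height m (default 0: ground-level dust).
#' @param sigma_z0 initial vertical plume spread m, representing the upwind
#'   extent of the source (default 10 for border lines).
#' @return a `line_source` object.
#' @export
line_source <- function(id, x1, y1, x2, y2, category, h = 0, sigma_z0 = 10) {
  if (x1 == x2 && y1 == y2) stop("line source endpoints must be distinct")
  stopifnot(sigma_z0 >= 0, h >= 0)
  structure(list(id = as.character(id), x1 = x1, y1 = y1, x2 = x2, y2 = y2,
                 h = h, sigma_z0 = sigma_z0, category = as.character(category),
                 type = "line"),
            class = "line_source")
}

#' Define a polygonal area source
#'
#' @param id character id.
#' @param px,py polygon vertex coordinates (simple polygon, not closed),
#'   projected meters.
#' @param category source-category label.
#' @param h release height m (default 0).
#' @param sigma_z0 initial vertical plume spread m (default 0).
#' @return an `area_source` object.
#' @export
area_source <- function(id, px, py, category, h = 0, sigma_z0 = 0) {
  stopifnot(length(px) == length(py), length(px) >= 3, sigma_z0 >= 0, h >= 0)
  if (.polygon_area(px, py) <= 0) stop("area source polygon must have positive area")
  structure(list(id = as.character(id), px = px, py = py, h = h,
                 sigma_z0 = sigma_z0, category = as.character(category),
                 type = "area"),
            class = "area_source")
}

#' Receptor table
#'
#' @param id character ids.
#' @param x,y coordinates, projected meters.
#' @param z height above ground m (default 2, typical monitor inlet).
#' @return data frame with columns id, x, y, z.
#' @export
receptors <- function(id, x, y, z = 2) {
  stopifnot(all(z >= 0), length(x) == length(y))
  data.frame(id = as.character(id), x = x, y = y, z = z,
             stringsAsFactors = FALSE)
}

#' Read a source geometry configuration
#'
#' Long-format CSV: one row per vertex, columns
#' `id,type,category,h,sigma_z0,vertex,x,y`. Lines have exactly 2 vertices;
#' areas at least 3 (polygon, not closed).
#'
#' @param path CSV path.
#' @return list of `line_source`/`area_source` objects.
#' @export
read_sources <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "type", "category", "h", "sigma_z0", "vertex", "x", "y")
  missing <- setdiff(required, names(df))
  if (length(missing)) stop("source file missing column(s): ",
                            paste(missing, collapse = ", "))
  lapply(split(df, df$id), function(g) {
    g <- g[order(g$vertex), ]
    if (g$type[1] == "line") {
      if (nrow(g) != 2) stop("line source ", g$id[1], " needs exactly 2 vertices")
      line_source(g$id[1], g$x[1], g$y[1], g$x[2], g$y[2], g$category[1],
                  h = g$h[1], sigma_z0 = g$sigma_z0[1])
    } else if (g$type[1] == "area") {
      area_source(g$id[1], g$x, g$y, g$category[1], h = g$h[1],
                  sigma_z0 = g$sigma_z0[1])
    } else stop("unknown source type: ", g$type[1])
  })
}

#' Write a source geometry configuration
#'
#' @param sources list of source objects.
#' @param path output CSV path.
#' @export
write_sources <- function(sources, path) {
  rows <- lapply(sources, function(s) {
    if (s$type == "line") {
      data.frame(id = s$id, type = "line", category = s$category, h = s$h,
                 sigma_z0 = s$sigma_z0, vertex = 1:2,
                 x = c(s$x1, s$x2), y = c(s$y1, s$y2))
    } else {
      data.frame(id = s$id, type = "area", category = s$category, h = s$h,
                 sigma_z0 = s$sigma_z0, vertex = seq_along(s$px),
                 x = s$px, y = s$py)
    }
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
}

# length of a line source, m
.line_length <- function(s) sqrt((s$x2 - s$x1)^2 + (s$y2 - s$y1)^2)

#' Default category grouping with length-proportional allocation
#'
#' A category's total emission rate is split among its member line sources
#' proportionally to line length (a category "unit emission" is spread along
#' the whole border it represents); a category with a single area source
#' carries weight 1.
#'
#' @param sources list of source objects.
#' @return data frame `id, category, weight`; weights sum to 1 within each
#'   category.
#' @export
default_grouping <- function(sources) {
  df <- do.call(rbind, lapply(sources, function(s) {
    data.frame(id = s$id, category = s$category,
               size = if (s$type == "line") .line_length(s) else 1,
               stringsAsFactors = FALSE)
  }))
  df$weight <- df$size / ave(df$size, df$category, FUN = sum)
  df$size <- NULL
  rownames(df) <- NULL
  df
}

# canonical category ordering: keep the valley-study order when those labels
# are present, otherwise alphabetical
.category_levels <- function(categories) {
  canonical <- c("West Desert", "Salton Sea", "East Desert", "Mexico", "Valley")
  u <- unique(categories)
  if (all(u %in% canonical)) canonical[canonical %in% u] else sort(u)
}
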
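make_spectrum_table <- function(con) {
  DBI::dbExecute(con, paste(
    "CREATE TABLE spectrum (id INTEGER PRIMARY KEY, title TEXT, data BLOB,",
    "creationdate TIMESTAMP, modificationdate TIMESTAMP)"
  ))
}

test_that("introspection detects types, keys and audit columns", {
  con <- sqlite_memory()
  on.exit(DBI::dbDisconnect(con))
  make_spectrum_table(con)
  d <- introspect(con, "spectrum")
  expect_s3_class(d, "table_descriptor")
  expect_identical(d$primary_key, "id")
  expect_true(d$pk_autogenerated)
  expect_setequal(d$audit_columns, c("creationdate", "modificationdate"))
  expect_identical(
    d$columns$type,
    c("integer", "text", "blob", "timestamp", "timestamp")
  )
  # composite non-auto key
  DBI::dbExecute(con, "CREATE TABLE pair (a TEXT, b TEXT, v REAL, PRIMARY KEY (a, b))")
  d2 <- introspect(con, "pair")
  expect_false(d2$pk_autogenerated)
  expect_identical(length(d2$primary_key), 2L)
  expect_error(introspect(con, "nope"), class = "protutils_unknown_table")
})

test_that("audit-named columns with wrong types are not treated as audit", {
  con <- sqlite_memory()
  on.exit(DBI::dbDisconnect(con))
  DBI::dbExecute(con, "CREATE TABLE odd (id INTEGER PRIMARY KEY, creationdate TEXT)")
  expect_warning(d <- introspect(con, "odd"), class = "protutils_audit_type")
  expect_identical(d$audit_columns, character())
})

test_that("generated source is deterministic, SQL-free for callers, and guarded", {
  con <- sqlite_memory()
  on.exit(DBI::dbDisconnect(con))
  make_spectrum_table(con)
  d <- introspect(con, "spectrum")
  src <- generate(d, "demo")
  expect_identical(src, generate(d, "demo"))
  # exactly the four persistence operations are exposed
  for (op in c("persist", "update", "retrieve", "delete")) {
    expect_identical(
      length(gregexpr(sprintf("\\.self\\$%s <- function", op), src)[[1]]), 1L,
      label = op
    )
  }
  # every statement is parameterized: no sprintf/paste into SQL, and the
  # only quote characters in SQL strings belong to quoted identifiers
  sqls <- regmatches(src, gregexpr("\"(INSERT|UPDATE|SELECT|DELETE)[^\n]*", src))[[1]]
  expect_gte(length(sqls), 4L) # the 4 CRUD statements (+ last-key shim)
  for (s in sqls) {
    expect_false(grepl("sprintf|paste", s))
    expect_true(grepl("\\?", s) || grepl("^\"SELECT", s))
  }
  # the accessor loads cleanly into a fresh environment
  factory <- load_accessor(src)
  acc <- factory()
  expect_false(acc$is_persisted())
  expect_false(acc$is_dirty())
  acc$set("title", "x")
  expect_true(acc$is_dirty())
  # descriptor without a primary key cannot be generated
  nopk <- table_descriptor(
    "bare",
    data.frame(name = "v", type = "text", nullable = TRUE,
               stringsAsFactors = FALSE),
    primary_key = character()
  )
  expect_error(generate(nopk), class = "protutils_cannot_generate")
  # multi-column autogenerated keys are rejected
  multi <- table_descriptor(
    "m",
    data.frame(name = c("a", "b"), type = "integer", nullable = FALSE,
               stringsAsFactors = FALSE),
    primary_key = c("a", "b"), pk_autogenerated = TRUE
  )
  expect_error(generate(multi), class = "protutils_cannot_generate")
})

test_that("a full CRUD cycle round-trips values, blobs and audit semantics", {
  con <- sqlite_memory()
  on.exit(DBI::dbDisconnect(con))
  make_spectrum_table(con)
  src <- generate(introspect(con, "spectrum"), "demo")
  set.seed(99)
  blob <- as.raw(sample(0:255, 1024, replace = TRUE))
  rep <- crud_roundtrip(
    src, con,
    values = list(title = "a spectrum", data = blob),
    mutate = list(title = "renamed")
  )
  expect_true(rep$pass)
  # the steps include the audit-column contracts
  expect_true(rep$steps[["creationdate_set"]])
  expect_true(rep$steps[["modificationdate_refreshed"]])
  expect_true(rep$steps[["creationdate_untouched"]])
  expect_true(rep$steps[["noop_update_zero_rows"]])
  expect_true(rep$steps[["second_delete_zero_rows"]])
})

test_that("random fixture schemas all survive the CRUD exercise", {
  con <- sqlite_memory()
  on.exit(DBI::dbDisconnect(con))
  for (s in 1:8) {
    sch <- make_schema(seed = 1000 + s, table_name = sprintf("t%d", s))
    DBI::dbExecute(con, sch$create_sql)
    rep <- crud_roundtrip(
      generate(introspect(con, sch$table_name), "dao"),
      con, sch$values, sch$mutate
    )
    expect_true(rep$pass, label = sprintf("schema %d", s))
  }
})

test_that("parent and child rows persist through the abstract interface", {
  con <- sqlite_memory()
  on.exit(DBI::dbDisconnect(con))
  DBI::dbExecute(con, "CREATE TABLE parent (id INTEGER PRIMARY KEY, name TEXT)")
  DBI::dbExecute(con, paste(
    "CREATE TABLE child (id INTEGER PRIMARY KEY, parent_id INTEGER",
    "REFERENCES parent(id), label TEXT)"
  ))
  parent_new <- load_accessor(generate(introspect(con, "parent"), "dao"))
  child_new <- load_accessor(generate(introspect(con, "child"), "dao"))
  DBI::dbBegin(con)
  p <- parent_new()
  p$set("name", "experiment")
  p$persist(con)
  expect_true(is.numeric(p$get("id")) || is.integer(p$get("id")))
  ch <- child_new()
  ch$set("parent_id", p$get("id"))
  ch$set("label", "replicate 1")
  ch$persist(con)
  DBI::dbCommit(con)
  joined <- DBI::dbGetQuery(con, paste(
    "SELECT parent.name, child.label FROM child",
    "JOIN parent ON parent.id = child.parent_id"
  ))
  expect_identical(nrow(joined), 1L)
  expect_identical(joined$name, "experiment")
})
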
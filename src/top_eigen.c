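/* Leading-k eigenpairs of a dense symmetric matrix via LAPACK dsyevr with
 * an index-range query (IL..IU = n-k+1..n).  For k << n this does one
 * tridiagonal reduction instead of the full eigendecomposition that
 * eigen() performs, which matters when projecting onto the top
 * eigenvectors of large random matrices. */

#define USE_FC_LEN_T
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Lapack.h>
#ifndef FCONE
# define FCONE
#endif

SEXP top_eigen_sym(SEXP A, SEXP kk)
{
    if (!isReal(A) || !isMatrix(A))
        error("'A' must be a numeric matrix");
    int n = INTEGER(getAttrib(A, R_DimSymbol))[0];
    int nc = INTEGER(getAttrib(A, R_DimSymbol))[1];
    if (n != nc) error("'A' must be square");
    int k = asInteger(kk);
    if (k < 1 || k > n) error("'k' out of range");

    /* dsyevr overwrites its input */
    double *a = (double *) R_alloc((size_t) n * n, sizeof(double));
    memcpy(a, REAL(A), (size_t) n * n * sizeof(double));

    SEXP w_sexp = PROTECT(allocVector(REALSXP, k));
    SEXP z_sexp = PROTECT(allocMatrix(REALSXP, n, k));
    double *w_all = (double *) R_alloc((size_t) n, sizeof(double));
    int *isuppz = (int *) R_alloc(2 * (size_t) k, sizeof(int));

    int il = n - k + 1, iu = n, m = 0, info = 0;
    double vl = 0.0, vu = 0.0, abstol = 0.0;
    int lwork = -1, liwork = -1, iwork_query = 0;
    double work_query = 0.0;

    /* workspace query */
    F77_CALL(dsyevr)("V", "I", "L", &n, a, &n, &vl, &vu, &il, &iu, &abstol,
                     &m, w_all, REAL(z_sexp), &n, isuppz,
                     &work_query, &lwork, &iwork_query, &liwork, &info
                     FCONE FCONE FCONE);
    if (info != 0) error("dsyevr workspace query failed (info = %d)", info);
    lwork = (int) work_query;
    liwork = iwork_query;
    double *work = (double *) R_alloc((size_t) lwork, sizeof(double));
    int *iwork = (int *) R_alloc((size_t) liwork, sizeof(int));

    F77_CALL(dsyevr)("V", "I", "L", &n, a, &n, &vl, &vu, &il, &iu, &abstol,
                     &m, w_all, REAL(z_sexp), &n, isuppz,
                     work, &lwork, iwork, &liwork, &info
                     FCONE FCONE FCONE);
    if (info != 0) error("dsyevr failed (info = %d)", info);
    if (m != k) error("dsyevr returned %d eigenpairs, expected %d", m, k);

    /* dsyevr returns the selected eigenvalues ascending; emit descending */
    double *w = REAL(w_sexp);
    double *z = REAL(z_sexp);
    for (int j = 0; j < k; j++)
        w[j] = w_all[k - 1 - j];
    for (int j = 0; j < k / 2; j++) {
        int j2 = k - 1 - j;
        for (int i = 0; i < n; i++) {
            double tmp = z[i + (size_t) j * n];
            z[i + (size_t) j * n] = z[i + (size_t) j2 * n];
            z[i + (size_t) j2 * n] = tmp;
        }
    }

    const char *names[] = {"values", "vectors", ""};
    SEXP out = PROTECT(mkNamed(VECSXP, names));
    SET_VECTOR_ELT(out, 0, w_sexp);
    SET_VECTOR_ELT(out, 1, z_sexp);
    UNPROTECT(3);
    return out;
}
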
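/* Real 3D FFT primitives backed by FFTW, used for kernel composition and
 * convolution-based chemical diffusion.  R arrays are column-major (first
 * index fastest); FFTW is row-major, so dimensions are passed reversed and
 * the half-spectrum is stored along the first R dimension (n1/2 + 1).
 */
#include <string.h>
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <fftw3.h>

static void get_dim3(SEXP a, int *n)
{
    SEXP dim = getAttrib(a, R_DimSymbol);
    if (dim == R_NilValue || LENGTH(dim) != 3)
        error("expected a 3-dimensional array");
    n[0] = INTEGER(dim)[0];
    n[1] = INTEGER(dim)[1];
    n[2] = INTEGER(dim)[2];
}

/* forward real-to-complex transform of a 3D double array */
SEXP C_rfft3(SEXP a_)
{
    int n[3];
    get_dim3(a_, n);
    size_t nreal = (size_t)n[0] * n[1] * n[2];
    size_t nc = (size_t)(n[0] / 2 + 1) * n[1] * n[2];

    double *in = fftw_alloc_real(nreal);
    fftw_complex *out = fftw_alloc_complex(nc);
    if (!in || !out)
        error("allocation failure in C_rfft3");
    fftw_plan p = fftw_plan_dft_r2c_3d(n[2], n[1], n[0], in, out,
                                       FFTW_ESTIMATE);
    memcpy(in, REAL(a_), sizeof(double) * nreal);
    fftw_execute(p);

    SEXP res = PROTECT(allocVector(CPLXSXP, (R_xlen_t)nc));
    Rcomplex *r = COMPLEX(res);
    for (size_t i = 0; i < nc; i++) {
        r[i].r = out[i][0];
        r[i].i = out[i][1];
    }
    SEXP rdim = PROTECT(allocVector(INTSXP, 3));
    INTEGER(rdim)[0] = n[0] / 2 + 1;
    INTEGER(rdim)[1] = n[1];
    INTEGER(rdim)[2] = n[2];
    setAttrib(res, R_DimSymbol, rdim);

    fftw_destroy_plan(p);
    fftw_free(in);
    fftw_free(out);
    UNPROTECT(2);
    return res;
}

/* inverse complex-to-real transform; spec has dims (n1/2+1, n2, n3) and
 * full_dim gives the real-space dims (n1, n2, n3); output is normalised. */
SEXP C_irfft3(SEXP spec_, SEXP full_dim_)
{
    if (LENGTH(full_dim_) != 3)
        error("full_dim must have length 3");
    int n[3];
    n[0] = INTEGER(full_dim_)[0];
    n[1] = INTEGER(full_dim_)[1];
    n[2] = INTEGER(full_dim_)[2];
    size_t nreal = (size_t)n[0] * n[1] * n[2];
    size_t nc = (size_t)(n[0] / 2 + 1) * n[1] * n[2];
    if ((size_t)XLENGTH(spec_) != nc)
        error("spectrum length does not match full_dim");

    fftw_complex *in = fftw_alloc_complex(nc);
    double *out = fftw_alloc_real(nreal);
    if (!in || !out)
        error("allocation failure in C_irfft3");
    fftw_plan p = fftw_plan_dft_c2r_3d(n[2], n[1], n[0], in, out,
                                       FFTW_ESTIMATE);
    Rcomplex *s = COMPLEX(spec_);
    for (size_t i = 0; i < nc; i++) {
        in[i][0] = s[i].r;
        in[i][1] = s[i].i;
    }
    fftw_execute(p);

    SEXP res = PROTECT(allocVector(REALSXP, (R_xlen_t)nreal));
    double scale = 1.0 / (double)nreal;
    double *r = REAL(res);
    for (size_t i = 0; i < nreal; i++)
        r[i] = out[i] * scale;
    SEXP rdim = PROTECT(allocVector(INTSXP, 3));
    INTEGER(rdim)[0] = n[0];
    INTEGER(rdim)[1] = n[1];
    INTEGER(rdim)[2] = n[2];
    setAttrib(res, R_DimSymbol, rdim);

    fftw_destroy_plan(p);
    fftw_free(in);
    fftw_free(out);
    UNPROTECT(2);
    return res;
}

/* elementwise integer power of a complex vector by binary exponentiation;
 * keeps full double precision for z^m with m up to a few thousand. */
SEXP C_cpow_int(SEXP z_, SEXP m_)
{
    int m = asInteger(m_);
    if (m < 0)
        error("m must be >= 0");
    R_xlen_t nz = XLENGTH(z_);
    SEXP res = PROTECT(duplicate(z_));
    Rcomplex *r = COMPLEX(res);
    Rcomplex *z = COMPLEX(z_);
    for (R_xlen_t i = 0; i < nz; i++) {
        double br = z[i].r, bi = z[i].i; /* base */
        double ar = 1.0, ai = 0.0;       /* accumulator */
        int e = m;
        while (e > 0) {
            if (e & 1) {
                double tr = ar * br - ai * bi;
                ai = ar * bi + ai * br;
                ar = tr;
            }
            e >>= 1;
            if (e) {
                double tr = br * br - bi * bi;
                bi = 2.0 * br * bi;
                br = tr;
            }
        }
        r[i].r = ar;
        r[i].i = ai;
    }
    UNPROTECT(1);
    return res;
}

static const R_CallMethodDef callMethods[] = {
    {"C_rfft3", (DL_FUNC)&C_rfft3, 1},
    {"C_irfft3", (DL_FUNC)&C_irfft3, 2},
    {"C_cpow_int", (DL_FUNC)&C_cpow_int, 2},
    {NULL, NULL, 0}
};

void R_init_vfheal(DllInfo *info)
{
    R_registerRoutines(info, NULL, callMethods, NULL, NULL);
    R_useDynamicSymbols(info, FALSE);
}
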
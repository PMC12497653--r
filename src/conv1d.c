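/* 1D same-padding convolution over (C, T, B) activation arrays.
 *
 * Weights are stored as (k, Cin, Cout).  Each (example, offset) pair is one
 * BLAS dgemm on contiguous memory: the input is copied once per example into
 * a zero-padded (Cin, T + k - 1) scratch block, and offset j contributes
 * W[j,,]^T  x  Xpad[, j:(j+T-1)] to the output.  The backward pass mirrors
 * this with accumulating dgemms for dX and dW.
 */

#define USE_FC_LEN_T
#include <R.h>
#include <Rinternals.h>
#include <R_ext/BLAS.h>
#include <string.h>
#ifndef FCONE
#define FCONE
#endif

static void dims3(SEXP x, int *d)
{
    SEXP dim = getAttrib(x, R_DimSymbol);
    d[0] = INTEGER(dim)[0];
    d[1] = INTEGER(dim)[1];
    d[2] = INTEGER(dim)[2];
}

SEXP C_conv1d_fwd(SEXP xs, SEXP ws, SEXP bs)
{
    int dx[3], dw[3];
    dims3(xs, dx);
    dims3(ws, dw);
    int Cin = dx[0], T = dx[1], B = dx[2];
    int k = dw[0], Cout = dw[2];
    int pad = (k - 1) / 2, Tp = T + k - 1;
    const double *X = REAL(xs), *W = REAL(ws), *bias = REAL(bs);

    SEXP ys = PROTECT(alloc3DArray(REALSXP, Cout, T, B));
    double *Y = REAL(ys);

    double *Xpad = (double *) R_alloc((size_t) Cin * Tp, sizeof(double));
    double *Wj = (double *) R_alloc((size_t) Cin * Cout, sizeof(double));
    const double one = 1.0;

    /* initialize output with the bias */
    for (size_t col = 0; col < (size_t) T * B; col++)
        memcpy(Y + col * Cout, bias, Cout * sizeof(double));

    for (int b = 0; b < B; b++) {
        memset(Xpad, 0, (size_t) Cin * Tp * sizeof(double));
        memcpy(Xpad + (size_t) Cin * pad, X + (size_t) b * Cin * T,
               (size_t) Cin * T * sizeof(double));
        for (int j = 0; j < k; j++) {
            /* Wj = W[j, , ] as (Cin, Cout) */
            for (int co = 0; co < Cout; co++)
                for (int ci = 0; ci < Cin; ci++)
                    Wj[ci + (size_t) co * Cin] =
                        W[j + (size_t) ci * k + (size_t) co * k * Cin];
            /* Y[, , b] += Wj^T (Cout x Cin) . Xpad[, j..j+T-1] (Cin x T) */
            F77_CALL(dgemm)("T", "N", &Cout, &T, &Cin,
                            &one, Wj, &Cin,
                            Xpad + (size_t) Cin * j, &Cin,
                            &one, Y + (size_t) b * Cout * T, &Cout
                            FCONE FCONE);
        }
    }
    UNPROTECT(1);
    return ys;
}

SEXP C_conv1d_bwd(SEXP xs, SEXP ws, SEXP dys)
{
    int dx[3], dw[3];
    dims3(xs, dx);
    dims3(ws, dw);
    int Cin = dx[0], T = dx[1], B = dx[2];
    int k = dw[0], Cout = dw[2];
    int pad = (k - 1) / 2, Tp = T + k - 1;
    const double *X = REAL(xs), *W = REAL(ws), *dY = REAL(dys);

    SEXP out = PROTECT(allocVector(VECSXP, 3));
    SEXP dxs = PROTECT(alloc3DArray(REALSXP, Cin, T, B));
    SEXP dws = PROTECT(alloc3DArray(REALSXP, k, Cin, Cout));
    SEXP dbs = PROTECT(allocVector(REALSXP, Cout));
    double *dX = REAL(dxs), *dWout = REAL(dws), *db = REAL(dbs);

    double *Xpad = (double *) R_alloc((size_t) Cin * Tp, sizeof(double));
    double *dXpad = (double *) R_alloc((size_t) Cin * Tp, sizeof(double));
    double *Wj = (double *) R_alloc((size_t) Cin * Cout, sizeof(double));
    double *dWj = (double *) R_alloc((size_t) Cin * Cout * k, sizeof(double));
    const double one = 1.0, zero = 0.0;

    memset(dWj, 0, (size_t) Cin * Cout * k * sizeof(double));
    memset(db, 0, Cout * sizeof(double));
    for (size_t col = 0; col < (size_t) T * B; col++)
        for (int co = 0; co < Cout; co++)
            db[co] += dY[col * Cout + co];

    for (int b = 0; b < B; b++) {
        memset(Xpad, 0, (size_t) Cin * Tp * sizeof(double));
        memcpy(Xpad + (size_t) Cin * pad, X + (size_t) b * Cin * T,
               (size_t) Cin * T * sizeof(double));
        memset(dXpad, 0, (size_t) Cin * Tp * sizeof(double));
        for (int j = 0; j < k; j++) {
            for (int co = 0; co < Cout; co++)
                for (int ci = 0; ci < Cin; ci++)
                    Wj[ci + (size_t) co * Cin] =
                        W[j + (size_t) ci * k + (size_t) co * k * Cin];
            /* dXpad[, j..] += Wj (Cin x Cout) . dY[, , b] (Cout x T) */
            F77_CALL(dgemm)("N", "N", &Cin, &T, &Cout,
                            &one, Wj, &Cin,
                            dY + (size_t) b * Cout * T, &Cout,
                            &one, dXpad + (size_t) Cin * j, &Cin
                            FCONE FCONE);
            /* dWj_j (Cin x Cout) += Xpad[, j..] (Cin x T) . dY[, , b]^T */
            F77_CALL(dgemm)("N", "T", &Cin, &Cout, &T,
                            &one, Xpad + (size_t) Cin * j, &Cin,
                            dY + (size_t) b * Cout * T, &Cout,
                            &one, dWj + (size_t) j * Cin * Cout, &Cin
                            FCONE FCONE);
        }
        memcpy(dX + (size_t) b * Cin * T, dXpad + (size_t) Cin * pad,
               (size_t) Cin * T * sizeof(double));
    }
    /* repack dWj blocks (Cin x Cout per offset) into (k, Cin, Cout) */
    for (int j = 0; j < k; j++)
        for (int co = 0; co < Cout; co++)
            for (int ci = 0; ci < Cin; ci++)
                dWout[j + (size_t) ci * k + (size_t) co * k * Cin] =
                    dWj[(size_t) j * Cin * Cout + ci + (size_t) co * Cin];
    (void) zero;
    SET_VECTOR_ELT(out, 0, dxs);
    SET_VECTOR_ELT(out, 1, dws);
    SET_VECTOR_ELT(out, 2, dbs);
    UNPROTECT(4);
    return out;
}
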
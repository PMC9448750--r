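Type	SBS1like	SBS5like	SBS18like	SBS40like
A[C>A]A	0.00078125	0.0104166666666667	0.0690625	0.0107573079647403
A[C>A]C	0.00078125	0.0104166666666667	0.0371875	0.0110964905844794
A[C>A]G	0.00078125	0.0104166666666667	0.0478125	0.011432762093834
A[C>A]T	0.00078125	0.0104166666666667	0.0584375	0.0117646825265756
C[C>A]A	0.00078125	0.0104166666666667	0.082875	0.012090830548454
C[C>A]C	0.00078125	0.0104166666666667	0.044625	0.0124098095435682
C[C>A]G	0.00078125	0.0104166666666667	0.057375	0.0127202535948906
C[C>A]T	0.00078125	0.0104166666666667	0.070125	0.0130208333333333
G[C>A]A	0.00078125	0.0104166666666667	0.05525	0.0133102616303104
G[C>A]C	0.00078125	0.0104166666666667	0.02975	0.0135872991094204
G[C>A]G	0.00078125	0.0104166666666667	0.03825	0.0138507594536462
G[C>A]T	0.00078125	0.0104166666666667	0.04675	0.0140995144853466
T[C>A]A	0.00078125	0.0104166666666667	0.0690625	0.0143324989972863
T[C>A]C	0.00078125	0.0104166666666667	0.0371875	0.0145487153140168
T[C>A]G	0.00078125	0.0104166666666667	0.0478125	0.0147472375640758
T[C>A]T	0.00078125	0.0104166666666667	0.0584375	0.0149272156447106
A[C>G]A	0.00078125	0.0104166666666667	0.0046875	0.0150878788621494
A[C>G]C	0.00078125	0.0104166666666667	0.0046875	0.0152285392318296
A[C>G]G	0.00078125	0.0104166666666667	0.0046875	0.0153485944244537
A[C>G]T	0.00078125	0.0104166666666667	0.0046875	0.0154475303452556
C[C>G]A	0.00078125	0.0104166666666667	0.0046875	0.0155249233354335
C[C>G]C	0.00078125	0.0104166666666667	0.0046875	0.0155804419863219
C[C>G]G	0.00078125	0.0104166666666667	0.0046875	0.0156138485585344
C[C>G]T	0.00078125	0.0104166666666667	0.0046875	0.015625
G[C>G]A	0.00078125	0.0104166666666667	0.0046875	0.0156138485585344
G[C>G]C	0.00078125	0.0104166666666667	0.0046875	0.0155804419863219
G[C>G]G	0.00078125	0.0104166666666667	0.0046875	0.0155249233354335
G[C>G]T	0.00078125	0.0104166666666667	0.0046875	0.0154475303452556
T[C>G]A	0.00078125	0.0104166666666667	0.0046875	0.0153485944244537
T[C>G]C	0.00078125	0.0104166666666667	0.0046875	0.0152285392318296
T[C>G]G	0.00078125	0.0104166666666667	0.0046875	0.0150878788621494
T[C>G]T	0.00078125	0.0104166666666667	0.0046875	0.0149272156447106
A[C>T]A	0.00833333333333333	0.0104166666666667	0.0046875	0.0147472375640758
A[C>T]C	0.00833333333333333	0.0104166666666667	0.0046875	0.0145487153140168
A[C>T]G	0.082	0.0104166666666667	0.0046875	0.0143324989972863
A[C>T]T	0.00833333333333333	0.0104166666666667	0.0046875	0.0140995144853466
C[C>T]A	0.00833333333333333	0.0104166666666667	0.0046875	0.0138507594536462
C[C>T]C	0.00833333333333333	0.0104166666666667	0.0046875	0.0135872991094204
C[C>T]G	0.06	0.0104166666666667	0.0046875	0.0133102616303104
C[C>T]T	0.00833333333333333	0.0104166666666667	0.0046875	0.0130208333333333
G[C>T]A	0.00833333333333333	0.0104166666666667	0.0046875	0.0127202535948906
G[C>T]C	0.00833333333333333	0.0104166666666667	0.0046875	0.0124098095435682
G[C>T]G	0.048	0.0104166666666667	0.0046875	0.012090830548454
G[C>T]T	0.00833333333333333	0.0104166666666667	0.0046875	0.0117646825265756
T[C>T]A	0.00833333333333333	0.0104166666666667	0.0046875	0.011432762093834
T[C>T]C	0.00833333333333333	0.0104166666666667	0.0046875	0.0110964905844794
T[C>T]G	0.66	0.0104166666666667	0.0046875	0.0107573079647403
T[C>T]T	0.00833333333333333	0.0104166666666667	0.0046875	0.0104166666666667
A[T>A]A	0.00078125	0.0104166666666667	0	0.010076025368593
A[T>A]C	0.00078125	0.0104166666666667	0	0.0097368427488539
A[T>A]G	0.00078125	0.0104166666666667	0	0.00940057123949933
A[T>A]T	0.00078125	0.0104166666666667	0	0.00906865080675771
C[T>A]A	0.00078125	0.0104166666666667	0	0.00874250278487937
C[T>A]C	0.00078125	0.0104166666666667	0	0.00842352378976516
C[T>A]G	0.00078125	0.0104166666666667	0	0.0081130797384427
C[T>A]T	0.00078125	0.0104166666666667	0	0.0078125
G[T>A]A	0.00078125	0.0104166666666667	0	0.00752307170302291
G[T>A]C	0.00078125	0.0104166666666667	0	0.00724603422391291
G[T>A]G	0.00078125	0.0104166666666667	0	0.00698257387968714
G[T>A]T	0.00078125	0.0104166666666667	0	0.00673381884798673
T[T>A]A	0.00078125	0.0104166666666667	0	0.00650083433604699
T[T>A]C	0.00078125	0.0104166666666667	0	0.00628461801931648
T[T>A]G	0.00078125	0.0104166666666667	0	0.00608609576925758
T[T>A]T	0.00078125	0.0104166666666667	0	0.00590611768862272
A[T>C]A	0	0.0104166666666667	0	0.00574545447118392
A[T>C]C	0	0.0104166666666667	0	0.00560479410150371
A[T>C]G	0	0.0104166666666667	0	0.00548473890887966
A[T>C]T	0	0.0104166666666667	0	0.00538580298807777
C[T>C]A	0	0.0104166666666667	0	0.00530840999789984
C[T>C]C	0	0.0104166666666667	0	0.0052528913470114
C[T>C]G	0	0.0104166666666667	0	0.00521948477479894
C[T>C]T	0	0.0104166666666667	0	0.00520833333333333
G[T>C]A	0	0.0104166666666667	0	0.00521948477479894
G[T>C]C	0	0.0104166666666667	0	0.0052528913470114
G[T>C]G	0	0.0104166666666667	0	0.00530840999789984
G[T>C]T	0	0.0104166666666667	0	0.00538580298807777
T[T>C]A	0	0.0104166666666667	0	0.00548473890887966
T[T>C]C	0	0.0104166666666667	0	0.00560479410150371
T[T>C]G	0	0.0104166666666667	0	0.00574545447118391
T[T>C]T	0	0.0104166666666667	0	0.00590611768862272
A[T>G]A	0.00078125	0.0104166666666667	0	0.00608609576925758
A[T>G]C	0.00078125	0.0104166666666667	0	0.00628461801931648
A[T>G]G	0.00078125	0.0104166666666667	0	0.00650083433604699
A[T>G]T	0.00078125	0.0104166666666667	0	0.00673381884798673
C[T>G]A	0.00078125	0.0104166666666667	0	0.00698257387968714
C[T>G]C	0.00078125	0.0104166666666667	0	0.00724603422391291
C[T>G]G	0.00078125	0.0104166666666667	0	0.0075230717030229
C[T>G]T	0.00078125	0.0104166666666667	0	0.0078125
G[T>G]A	0.00078125	0.0104166666666667	0	0.0081130797384427
G[T>G]C	0.00078125	0.0104166666666667	0	0.00842352378976516
G[T>G]G	0.00078125	0.0104166666666667	0	0.00874250278487937
G[T>G]T	0.00078125	0.0104166666666667	0	0.0090686508067577
T[T>G]A	0.00078125	0.0104166666666667	0	0.00940057123949933
T[T>G]C	0.00078125	0.0104166666666667	0	0.0097368427488539
T[T>G]G	0.00078125	0.0104166666666667	0	0.010076025368593
T[T>G]T	0.00078125	0.0104166666666667	0	0.0104166666666667
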
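# Builds the two QSO residue-distance matrices shipped in inst/extdata.
aa <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S","T","V","W","Y")
# Grantham (1974) properties: composition, polarity, molecular volume
comp <- c(A=0,C=2.75,D=1.38,E=0.92,F=0,G=0.74,H=0.58,I=0,K=0.33,L=0,M=0,
          N=1.33,P=0.39,Q=0.89,R=0.65,S=1.42,T=0.71,V=0,W=0.13,Y=0.20)
pol  <- c(A=8.1,C=5.5,D=13.0,E=12.3,F=5.2,G=9.0,H=10.4,I=5.2,K=11.3,L=4.9,
          M=5.7,N=11.6,P=8.0,Q=10.5,R=10.5,S=9.2,T=8.6,V=5.9,W=5.4,Y=6.2)
vol  <- c(A=31,C=55,D=54,E=83,F=132,G=3,H=96,I=111,K=119,L=111,M=105,
          N=56,P=32.5,Q=85,R=124,S=32,T=61,V=84,W=170,Y=136)
g <- matrix(0, 20, 20, dimnames = list(aa, aa))
for (i in 1:20) for (j in 1:20)
  g[i, j] <- 50.723 * sqrt(1.833*(comp[i]-comp[j])^2 +
                           0.1018*(pol[i]-pol[j])^2 +
                           0.000399*(vol[i]-vol[j])^2)
g <- round(g)
stopifnot(g["L","I"] == 5, g["R","K"] == 26, isSymmetric(g))
write.table(g, "inst/extdata/qso_grantham_matrix.tsv",
            sep = "\t", quote = FALSE, col.names = NA)
# Synthetic physicochemical stand-in (Schneider-Wrede values unavailable
# offline): Kyte-Doolittle hydrophobicity, Hopp-Woods hydrophilicity,
# side-chain mass; z-scored per scale, RMS difference.
kd <- c(A=1.8,C=2.5,D=-3.5,E=-3.5,F=2.8,G=-0.4,H=-3.2,I=4.5,K=-3.9,L=3.8,
        M=1.9,N=-3.5,P=-1.6,Q=-3.5,R=-4.5,S=-0.8,T=-0.7,V=4.2,W=-0.9,Y=-1.3)
hw <- c(A=-0.5,C=-1.0,D=3.0,E=3.0,F=-2.5,G=0.0,H=-0.5,I=-1.8,K=3.0,L=-1.8,
        M=-1.3,N=0.2,P=0.0,Q=0.2,R=3.0,S=0.3,T=-0.4,V=-1.5,W=-3.4,Y=-2.3)
ms <- c(A=15,C=47,D=59,E=73,F=91,G=1,H=82,I=57,K=73,L=57,M=75,
        N=58,P=42,Q=72,R=101,S=31,T=45,V=43,W=130,Y=107)
z <- function(x) (x - mean(x)) / sd(x)
P <- cbind(z(kd), z(hw), z(ms))
s <- matrix(0, 20, 20, dimnames = list(aa, aa))
for (i in 1:20) for (j in 1:20) s[i, j] <- sqrt(mean((P[i,]-P[j,])^2))
s <- round(s, 4)
write.table(s, "inst/extdata/qso_physchem_synthetic_matrix.tsv",
            sep = "\t", quote = FALSE, col.names = NA)
cat("ok\n")
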
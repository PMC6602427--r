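#Pdb;Mutation(s)_PDB;Mutation(s)_cleaned;Affinity_mut_parsed;Affinity_wt_parsed;Temperature
1ABC_A_B;LA38G;LA38G;1.0E-07;1.0E-09;298
1ABC_A_B;LA38G;LA38G;1.2E-07;1.0E-09;298
1ABC_A_B;EA40K;EA40K;1.0E-05;1.0E-09;298
1ABC_A_B;EA40K;EA40K;2.0E-02;1.0E-09;298
1ABC_A_B;LA38G,EA40K;LA38G,EA40K;1.0E-06;1.0E-09;298
2XYZ_C_D;GC10A;GC10A;5.0E-08;1.0E-09;298
2XYZ_C_D;AD25W;AD25W;1.0E-10;1.0E-09;298
2XYZ_C_D;SD30T;SD30T;3.0E-09;1.0E-09;298(assumed)
2XYZ_C_D;TD31I;TD31I;8.0E-09;1.0E-09;
3PQR_A_B;YA5F;YA5F;2.0E-08;5.0E-09;310
3PQR_A_B;KA7M;KA7M;1.0E-08;5.0E-09;298
3PQR_A_B;RB12Q;RB12Q;4.0E-08;5.0E-09;298
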
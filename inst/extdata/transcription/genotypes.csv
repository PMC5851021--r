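family,species,vector
Calliphoridae,Lucilia ampullacea,ACTCGT
Calliphoridae,Lucilia caesar,ACTCAT
Calliphoridae,Lucilia illustris,ACTTAT
Calliphoridae,Chrysomya megacephala,ACATGT
Calliphoridae,Chrysomya pinguis,ACATAT
Calliphoridae,Triceratopyga calliphoroides,AATTAC
Calliphoridae,Calliphora lata,AATTAT
Calliphoridae,Phormia regina,ATAAAT
Calliphoridae,Calliphora vicina,AGTTAC
Calliphoridae,Lucilia sericata,TCTTAT
Calliphoridae,Aldrichina grahami,TACCAC
Sarcophagidae,Parasarcophaga albiceps,TATA
Sarcophagidae,Sarcophaga similis,TAAA
Sarcophagidae,Sarcophaga haemorrhoidalis,TTAA
Sarcophagidae,Sarcophaga peregrina,TGAA
Sarcophagidae,Sarcophaga melanura,CAAA
Sarcophagidae,Sarcophaga crassipalpis,CAAG
Sarcophagidae,Sarcophaga dux,AGAA
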
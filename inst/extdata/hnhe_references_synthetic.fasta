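>IHMU synthetic I-HmuI-like reference (catalytic D74 H75 N96)
HKPWQYERWREINTGQCFCIPIGCNSQHRQYADITGGWMGMRQHMHAMRMGRILINKISC
NNNDIIMLPQYDHDHPKYVRCCRVNNHTKEHFSLVNMDTYVPDECHKIMTQKSFHMVCYS
SPVQLCYGEDLKWSCCIMIGVPWLAHPIHDEHQMDVNNFHDFWRAAVPGNPWAFFAHSMH
SYEFLPHLPA
>PACI synthetic PacI-like reference (catalytic D49 H50 N80)
NELSMVCRHYNPPRNDGIDLHHSLKPISEVEKGVRGARRLFVWNPEWPDHAPQGQVRKYY
MWFCNMFYFCPALQRADIWNEKPCSNAEAAMKPQQITPENWFWWTLARNQSNVWLFDDTH
WAMQWMPWCDQHKPTFHVMRKFIQLHQSHVAVNKQRPPEK
>GVE2 synthetic GVE2-like reference (catalytic D99 H100 H130)
YTRYQTRQFYSKFMFPMHETLFVWPQGLILRDESLILKGIQCEWFMPVVLAIDLIPVQFA
MTPSETGRSLTESGNQEHRRPIWHVPEANLFQCHRKFNDHRYGCQEYILCNMFLNDDWAS
CDRENIMHSHLNCNKCDVDMGAWIMGTFNTDVLCREPMLCRACIVSREHDIFGMGSLLIY
SLCLTTVHLWLYDVQYANMPREVQFNNVHRQMIMYITGTH
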
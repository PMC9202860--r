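# Parent-education checklist, adapted from the NICE neonatal-jaundice
# communication guidance. Items common to every advice tier come first;
# tier-specific items follow. English (en) and Indonesian (id).
common:
  - en: "Explain that newborn jaundice is common and usually harmless, but that high bilirubin levels can be dangerous if untreated."
    id: "Jelaskan bahwa kuning pada bayi baru lahir sering terjadi dan biasanya tidak berbahaya, tetapi kadar bilirubin yang tinggi dapat berbahaya bila tidak diobati."
  - en: "Encourage frequent breastfeeding; do not interrupt feeding because of jaundice."
    id: "Anjurkan menyusui sesering mungkin; jangan hentikan pemberian ASI karena bayi kuning."
  - en: "Show the family how to check the baby for jaundice in natural light, including the whites of the eyes and the gums."
    id: "Tunjukkan kepada keluarga cara memeriksa kuning pada bayi di bawah cahaya alami, termasuk bagian putih mata dan gusi."
  - en: "Explain which warning signs (poor feeding, drowsiness, high-pitched cry, arching) require immediate medical attention."
    id: "Jelaskan tanda bahaya (malas menyusu, mengantuk berlebihan, tangisan melengking, tubuh melengkung) yang memerlukan pertolongan medis segera."
  - en: "Provide a contact point for urgent questions and reassure the family that asking for review is always appropriate."
    id: "Berikan kontak untuk pertanyaan darurat dan yakinkan keluarga bahwa meminta pemeriksaan ulang selalu tepat."
no_treatment:
  - en: "Explain that the bilirubin level is currently below the treatment threshold and no treatment is needed now."
    id: "Jelaskan bahwa kadar bilirubin saat ini di bawah ambang pengobatan dan belum memerlukan terapi."
  - en: "Agree a follow-up plan: when and where the bilirubin will be re-checked."
    id: "Sepakati rencana kontrol: kapan dan di mana kadar bilirubin akan diperiksa ulang."
  - en: "Advise the family to return earlier if the jaundice deepens or spreads, or if warning signs appear."
    id: "Anjurkan keluarga untuk kembali lebih awal bila kuning bertambah atau meluas, atau bila muncul tanda bahaya."
start_phototherapy:
  - en: "Explain what phototherapy is, why it is needed, and that it is a safe and effective treatment."
    id: "Jelaskan apa itu fototerapi, mengapa diperlukan, dan bahwa fototerapi adalah pengobatan yang aman dan efektif."
  - en: "Explain that the baby's eyes will be protected and that short breaks for feeding and cuddling are possible."
    id: "Jelaskan bahwa mata bayi akan dilindungi dan bahwa jeda singkat untuk menyusui dan menggendong masih memungkinkan."
  - en: "Explain that bilirubin will be re-measured during treatment to decide when phototherapy can stop."
    id: "Jelaskan bahwa bilirubin akan diperiksa ulang selama pengobatan untuk menentukan kapan fototerapi dapat dihentikan."
  - en: "Mention possible temporary side effects (rash, loose stools, temperature instability) and how they are managed."
    id: "Sampaikan kemungkinan efek samping sementara (ruam, mencret, suhu tidak stabil) dan cara penanganannya."
intensive_pt_consider_exchange:
  - en: "Explain that the bilirubin level is dangerously high and intensive phototherapy must start immediately."
    id: "Jelaskan bahwa kadar bilirubin sangat tinggi dan fototerapi intensif harus segera dimulai."
  - en: "Explain what an exchange transfusion is and why it may be needed if intensive phototherapy is not sufficient."
    id: "Jelaskan apa itu transfusi tukar dan mengapa mungkin diperlukan bila fototerapi intensif tidak cukup."
  - en: "Explain the risk of bilirubin-induced brain injury and why urgent treatment reduces that risk."
    id: "Jelaskan risiko kerusakan otak akibat bilirubin dan mengapa pengobatan segera menurunkan risiko tersebut."
  - en: "Explain the follow-up examinations (neurological assessment, hearing test) that will be arranged after treatment."
    id: "Jelaskan pemeriksaan lanjutan (penilaian neurologis, tes pendengaran) yang akan dijadwalkan setelah pengobatan."
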